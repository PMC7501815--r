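# File formats: genotype parameter files (YAML), result CSVs and run
# metadata. All text is UTF-8, CSVs have headers and '.' decimals, ranks
# are 1-based acropetal.

genotype_keys <- c("n_final", "a_tip", "b_tip", "a_ll1", "b_ll1",
                   "a6", "b", "c", "w6", "r_rad")

#' Read genotype parameter sets (and species-constant overrides)
#'
#' Reads a YAML file with one block per genotype under a top-level
#' `genotypes:` mapping; each block must provide exactly the ten genotypic
#' keys (`n_final, a_tip, b_tip, a_ll1, b_ll1, a6, b, c, w6, r_rad`). An
#' optional top-level `constants:` block overrides individual species
#' constants. Unknown keys trigger a warning; missing keys an error naming
#' the key and genotype.
#'
#' @param path Path to the YAML file.
#' @return A list with `genotypes` (list of [genotype_parameters()]) and
#'   `constants` (a [species_constants()], defaults plus any overrides).
#' @export
read_genotypes <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$genotypes) || !length(doc$genotypes))
    stop("no 'genotypes' block found in ", path, call. = FALSE)
  gs <- lapply(names(doc$genotypes), function(nm) {
    block <- doc$genotypes[[nm]]
    miss <- setdiff(genotype_keys, names(block))
    if (length(miss))
      stop("genotype '", nm, "' is missing key(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    extra <- setdiff(names(block), genotype_keys)
    if (length(extra))
      warning("genotype '", nm, "': ignoring unknown key(s): ",
              paste(extra, collapse = ", "), call. = FALSE)
    do.call(genotype_parameters, c(block[genotype_keys], list(name = nm)))
  })
  names(gs) <- names(doc$genotypes)
  constants <- species_constants()
  if (!is.null(doc$constants)) {
    known <- names(unclass(species_constants()))
    extra <- setdiff(names(doc$constants), known)
    if (length(extra))
      warning("ignoring unknown constant(s): ",
              paste(extra, collapse = ", "), call. = FALSE)
    ov <- doc$constants[intersect(names(doc$constants), known)]
    constants <- do.call(species_constants,
                         utils::modifyList(as.list(unclass(constants)), ov))
    message("species constants overridden: ",
            paste(names(ov), collapse = ", "))
  }
  list(genotypes = gs, constants = constants)
}

#' Write simulation results to a directory
#'
#' Writes `schedule.csv`, `daily.csv` and `final_profile.csv` (UTF-8 CSVs
#' with headers; thermal times rounded to 4 decimals) plus `run_meta.json`
#' recording the genotype parameters, species constants, width floor and
#' any flags, so a run can be reproduced exactly from its outputs.
#'
#' @param result A [simulate_plant()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, dir) {
  if (!inherits(result, "plant_simulation"))
    stop("'result' must be a plant_simulation", call. = FALSE)
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", dir, call. = FALSE)
  r4 <- function(d) {
    num <- vapply(d, is.numeric, logical(1)) &
      !vapply(d, is.integer, logical(1))
    d[num] <- lapply(d[num], round, digits = 4)
    d
  }
  paths <- file.path(dir, c("schedule.csv", "daily.csv",
                            "final_profile.csv", "run_meta.json"))
  utils::write.csv(r4(as.data.frame(result$schedule)), paths[1L],
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(r4(result$daily), paths[2L], row.names = FALSE,
                   fileEncoding = "UTF-8")
  utils::write.csv(r4(result$final_profile), paths[3L], row.names = FALSE,
                   fileEncoding = "UTF-8")
  meta <- list(package_version = as.character(utils::packageVersion("phyllosim")),
               genotype = unclass(result$genotype),
               constants = unclass(result$constants),
               width_floor = result$width_floor,
               flags = result$flags)
  jsonlite::write_json(meta, paths[4L], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Read back a final-profile CSV
#'
#' @param path Path to a `final_profile.csv` written by [write_results()].
#' @return A data frame `rank, length_mm, width_mm`.
#' @export
read_final_profile <- function(path) {
  utils::read.csv(path, fileEncoding = "UTF-8")
}
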