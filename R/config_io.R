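#' Read and write model configuration files
#'
#' The model stack is serializable as plain YAML (or JSON) so that a
#' simulation setup can be shipped next to its outputs: `compound.yaml`
#' (compound properties), `kp.yaml` (tissue partition map) and
#' `pbpk_params.yaml` (free parameters). A directory holding any subset of
#' these files can be loaded in one call; missing files fall back to the
#' package defaults.
#'
#' @param x Object to write (`compound_properties`, named Kp vector, or
#'   `pbpk_parameters`).
#' @param path File path; extension `.yaml`/`.yml` or `.json` picks the
#'   format.
#' @return `write_model_config` returns `path` invisibly.
#' @export
write_model_config <- function(x, path) {
  obj <- if (is.numeric(x) && !is.null(names(x))) as.list(x) else unclass(x)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

read_config_file <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' @rdname write_model_config
#' @param dir Directory containing `compound.yaml`, `kp.yaml`,
#'   `pbpk_params.yaml` (any subset, `.json` variants allowed).
#' @return `load_model_config` returns a list with elements `compound`,
#'   `partition`, `params`.
#' @export
load_model_config <- function(dir) {
  find <- function(stem) {
    hits <- list.files(dir, pattern = paste0("^", stem, "\\.(ya?ml|json)$"),
                       full.names = TRUE)
    if (length(hits)) hits[1] else NULL
  }
  cmp_file <- find("compound")
  kp_file <- find("kp")
  par_file <- find("pbpk_params")
  compound <- if (is.null(cmp_file)) default_compound() else
    do.call(compound_properties, read_config_file(cmp_file))
  partition <- if (is.null(kp_file)) default_partition_coefficients() else
    unlist(read_config_file(kp_file))
  params <- if (is.null(par_file)) pbpk_parameters() else
    do.call(pbpk_parameters, read_config_file(par_file))
  list(compound = compound, partition = partition, params = params)
}
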