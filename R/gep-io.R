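#' Serialize a GEP model to JSON
#'
#' Writes the gene symbol strings, Dc indices, constant pools, linking
#' function, rounding threshold and marker order of a fitted or hand-built
#' chromosome. Constants are stored at full precision so that
#' [read_gep_model()] round-trips bit-exactly.
#'
#' @param fit A `gep_fit` (or a list with `best`, `structure`, `markers`,
#'   `threshold`).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_gep_model <- function(fit, path) {
  s <- fit$structure
  genes <- lapply(fit$best$genes, function(g) {
    # constants as %.17g strings: decimal JSON numbers do not round-trip
    # doubles bit-exactly through every writer, strings do
    list(symbols = s$symbol_names[g$symbols], dc = g$dc,
         consts = sprintf("%.17g", g$consts))
  })
  doc <- list(
    format = "gepdx-model",
    markers = fit$markers,
    head_length = s$h,
    constants_per_gene = s$n_const,
    linking = fit$best$linking,
    active = fit$best$active,
    threshold = fit$threshold,
    genes = genes
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a GEP model from JSON
#'
#' @param path Path written by [write_gep_model()].
#' @return A `gep_fit`-like list usable with [predict.gep_fit()].
#' @export
read_gep_model <- function(path) {
  if (!file.exists(path)) format_error(sprintf("No such file: %s.", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "gepdx-model")) {
    format_error(sprintf("%s is not a gepdx model file.", path))
  }
  s <- gene_structure(doc$head_length, doc$markers, gep_function_set(),
                      doc$constants_per_gene)
  ids <- seq_along(s$symbol_names)
  names(ids) <- s$symbol_names
  genes <- lapply(seq_len(nrow(doc$genes)), function(i) {
    g <- doc$genes[i, ]
    sym <- ids[unlist(g$symbols)]
    if (anyNA(sym)) format_error("Unknown symbol in model gene string.")
    structure(list(symbols = unname(as.integer(sym)),
                   dc = as.integer(unlist(g$dc)),
                   consts = as.numeric(unlist(g$consts))),
              class = "gep_gene")
  })
  chrom <- structure(list(genes = genes, active = as.integer(doc$active),
                          linking = doc$linking), class = "gep_chromosome")
  for (g in chrom$genes) validate_gene(g, s)
  structure(list(best = chrom, structure = s, markers = doc$markers,
                 threshold = doc$threshold),
            class = "gep_fit")
}
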