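#' Writers for the pipeline's TSV formats
#'
#' Each writer emits exactly the layout the corresponding reader
#' expects, so simulated data can round-trip through files.
#'
#' @param t,profiles,d,m Objects produced by the simulators.
#' @param path Output TSV path (two paths for the count matrix).
#' @name evoiso_writers
NULL

#' @rdname evoiso_writers
#' @export
write_mating_tsv <- function(t, path) {
  pops <- rownames(t)
  d <- expand.grid(female_pop = pops, male_pop = pops,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$count <- as.integer(t[cbind(d$female_pop, d$male_pop)])
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname evoiso_writers
#' @export
write_chc_tsv <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname evoiso_writers
#' @export
write_diallel_tsv <- function(d, path) {
  utils::write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname evoiso_writers
#' @param meta_path Output path of the sample-metadata TSV.
#' @export
write_counts_tsv <- function(m, path, meta_path) {
  d <- data.frame(gene_id = rownames(m$counts), m$counts,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- m$meta
  meta$lib_size <- m$lib_sizes
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
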