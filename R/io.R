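#' Tab-separated writers and readers for the pipeline's data objects
#'
#' All files are tab-separated with a single header line; positions are
#' 1-based kbp. Genotype calls are written as P1/P2/NA.
#'
#' @param map,genotypes,x,traits,track The object to write.
#' @param path Output file path.
#' @name wineqtl-io
NULL

#' @rdname wineqtl-io
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[, c("marker_id", "chromosome", "pos_kbp", "pos_cM")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname wineqtl-io
#' @export
read_marker_map <- function(path) {
  map <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  class(map) <- c("marker_map", "data.frame")
  validate_marker_map(map)
  map
}

#' @rdname wineqtl-io
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(marker_id = rownames(genotypes$calls), genotypes$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname wineqtl-io
#' @param map A \code{marker_map} matching the stored marker ids.
#' @export
read_genotypes <- function(path, map) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- df$marker_id
  stopifnot(identical(rownames(calls), map$marker_id))
  structure(list(map = map, calls = calls, segregant_ids = colnames(calls)),
            class = "genotype_matrix")
}

#' @rdname wineqtl-io
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene = x$gene_annot$gene_id, chrom = x$gene_annot$chromosome,
                   pos_kbp = x$gene_annot$pos_kbp, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname wineqtl-io
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  values <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(values) <- df$gene
  structure(list(values = values,
                 gene_annot = data.frame(gene_id = df$gene, chromosome = df$chrom,
                                         pos_kbp = df$pos_kbp, stringsAsFactors = FALSE),
                 sample_ids = colnames(values)),
            class = "expression_matrix")
}

#' @rdname wineqtl-io
#' @export
write_traits <- function(traits, path) {
  rows <- lapply(names(traits), function(nm) {
    t <- traits[[nm]]
    rbind(data.frame(trait = nm, unit = "segregant", id = names(t$values),
                     value = unname(t$values), stringsAsFactors = FALSE),
          data.frame(trait = nm, unit = "parent1",
                     id = sprintf("P1_rep%d", seq_along(t$parent1)),
                     value = t$parent1, stringsAsFactors = FALSE),
          data.frame(trait = nm, unit = "parent2",
                     id = sprintf("P2_rep%d", seq_along(t$parent2)),
                     value = t$parent2, stringsAsFactors = FALSE))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname wineqtl-io
#' @export
read_traits <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  out <- lapply(split(df, df$trait), function(d) {
    list(values = stats::setNames(d$value[d$unit == "segregant"], d$id[d$unit == "segregant"]),
         parent1 = d$value[d$unit == "parent1"],
         parent2 = d$value[d$unit == "parent2"])
  })
  structure(out, class = "trait_table")
}

#' @rdname wineqtl-io
#' @export
write_probe_track <- function(track, path) {
  utils::write.table(as.data.frame(track)[, c("probe_id", "chrom", "pos_kbp", "log_signal")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname wineqtl-io
#' @export
read_probe_track <- function(path) {
  track <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  class(track) <- c("probe_track", "data.frame")
  track
}
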