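#' Read and write the plain-text interchange formats
#'
#' Marker maps, phased haplotypes and marker effects travel as
#' tab-separated text.  All writers/readers round-trip losslessly.
#'
#' Marker map TSV: columns `marker_id`, `chrom`, `pos_cM`.
#' Haplotype TSV: 2N rows (individual i's maternal haplotype then its
#' paternal one), one 0/1 column per marker, header = marker ids.
#' Effects TSV: columns `marker_id`, `effect`.
#'
#' @param map a `marker_map`.
#' @param path file path.
#' @name formats
NULL

#' @rdname formats
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(
    data.frame(marker_id = map$marker_id, chrom = map$chrom,
               pos_cM = map$pos_cM),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname formats
#' @export
read_marker_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "pos_cM")
  if (!all(need %in% names(df)))
    stop("marker map must have columns ", paste(need, collapse = ", "))
  chroms <- unique(df$chrom)
  sizes <- vapply(chroms, function(ch) sum(df$chrom == ch), integer(1L))
  build_marker_map(sizes, pos_cM = df$pos_cM, marker_id = df$marker_id)
}

#' @rdname formats
#' @param pop a `population` (hard).
#' @export
write_haplotypes <- function(pop, map, path) {
  m <- pop$m
  H <- matrix(0L, 2L * pop$N, m)
  H[seq(1L, 2L * pop$N, by = 2L), ] <- pop$w[, seq_len(m)]
  H[seq(2L, 2L * pop$N, by = 2L), ] <- pop$w[, m + seq_len(m)]
  colnames(H) <- map$marker_id
  utils::write.table(H, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname formats
#' @export
read_haplotypes <- function(path, map) {
  H <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  if (ncol(H) != map$m)
    stop("haplotype file has ", ncol(H), " markers, map has ", map$m)
  if (nrow(H) %% 2L != 0L) stop("haplotype file must have 2N rows")
  bad <- which(!(H == 0L | H == 1L), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-binary haplotype entry '%s' at row %d, column %d",
                 H[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], bad[1L, 2L]))
  N <- nrow(H) %/% 2L
  w <- cbind(H[seq(1L, 2L * N, by = 2L), , drop = FALSE],
             H[seq(2L, 2L * N, by = 2L), , drop = FALSE])
  new_population(w, generation = 0L)
}

#' @rdname formats
#' @param trait a `trait_arch`.
#' @export
write_effects <- function(trait, map, path) {
  utils::write.table(
    data.frame(marker_id = map$marker_id, effect = trait$beta),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname formats
#' @export
read_effects <- function(path, map) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("marker_id", "effect") %in% names(df)))
    stop("effects file must have columns marker_id, effect")
  unknown <- setdiff(df$marker_id, map$marker_id)
  if (length(unknown) > 0L)
    stop("unknown marker_id in effects file: ", unknown[1L])
  if (length(df$marker_id) != map$m) stop("effects file must cover every marker")
  beta <- df$effect[match(map$marker_id, df$marker_id)]
  new_trait(beta, map)
}

#' Export a population as a phased VCF
#'
#' Minimal VCFv4.2 with phased GT fields ("0|1"-style); positions are the
#' cM coordinates scaled to integer base pairs (1 cM = 10000 bp) purely
#' for interoperability.
#'
#' @param pop a hard `population`.
#' @param map a `marker_map`.
#' @param path output path.
#' @export
write_vcf <- function(pop, map, path) {
  m <- map$m
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=breedgrad",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  samples <- paste0("IND", seq_len(pop$N))
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  gt <- matrix(paste(pop$w[, seq_len(m)], pop$w[, m + seq_len(m)], sep = "|"),
               pop$N, m)
  pos_bp <- as.integer(round(map$pos_cM * 1e4)) + 1L
  for (j in seq_len(m)) {
    writeLines(paste(c(map$chrom[j], pos_bp[j], map$marker_id[j], "A", "T",
                       ".", "PASS", ".", "GT", gt[, j]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Audit dump of pair features
#'
#' @param feats a `pair_features`.
#' @param path output TSV path.
#' @export
write_features <- function(feats, path) {
  df <- data.frame(pair = seq_len(nrow(feats$pairs)),
                   kM = feats$pairs[, 1L], kP = feats$pairs[, 2L])
  raw <- feats$omega_raw
  colnames(raw) <- paste0(colnames(raw), "_raw")
  std <- feats$omega
  colnames(std) <- paste0(colnames(std), "_std")
  utils::write.table(cbind(df, raw, std), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
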