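#' Parse a QTL interval specification
#'
#' Accepts the usual `chrom:start-end` string (1-based, inclusive end).
#' Optional QTL annotations (name, LOD score, percent variance explained) are
#' carried through to reports untouched.
#'
#' @param spec interval string like `"chr3:179000000-181000000"`.
#' @param name optional interval name (defaults to the spec string).
#' @param lod,pve optional QTL mapping annotations.
#' @return list of class `qtl_interval` with fields `chrom`, `start`, `end`,
#'   `name`, `lod`, `pve`.
#' @export
parse_interval <- function(spec, name = NULL, lod = NULL, pve = NULL) {
  m <- regmatches(spec, regexec("^([^:]+):([0-9]+)-([0-9]+)$", spec))[[1]]
  if (length(m) != 4) stop("cannot parse interval spec: ", spec,
                           " (expected chrom:start-end)")
  start <- as.integer(m[3]); end <- as.integer(m[4])
  if (start < 1 || start > end) stop("invalid interval bounds in: ", spec)
  structure(list(chrom = m[2], start = start, end = end,
                 name = if (is.null(name)) spec else name,
                 lod = lod, pve = pve),
            class = "qtl_interval")
}

#' Gene models overlapping a QTL interval
#'
#' Imports `gene` features from a GFF3 file and returns those whose span
#' overlaps the interval by at least one base pair (any-overlap semantics:
#' QTL boundaries are imprecise, so containment is not required), sorted by
#' start coordinate.
#'
#' @param gff path to a GFF3 file with `gene` features carrying `ID=`
#'   attributes.
#' @param interval a [parse_interval()] object or a `chrom:start-end` string.
#' @return data.frame with columns `id`, `chrom`, `start`, `end`, `strand`.
#' @export
genes_in_interval <- function(gff, interval) {
  if (is.character(interval)) interval <- parse_interval(interval)
  stopifnot(inherits(interval, "qtl_interval"))
  models <- read_gene_models(gff)
  if (!interval$chrom %in% models$chrom) {
    warning("no gene features on chromosome ", interval$chrom)
    return(models[0, , drop = FALSE])
  }
  hit <- models$chrom == interval$chrom &
    models$start <= interval$end & models$end >= interval$start
  out <- models[hit, , drop = FALSE]
  out <- out[order(out$start, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene models from GFF3
#'
#' @param gff path to a GFF3 file.
#' @return data.frame of all `gene` features: `id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_models <- function(gff) {
  if (!file.exists(gff)) stop("GFF3 file not found: ", gff)
  lines <- readLines(gff)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nf != 9))
    stop(sprintf("malformed GFF3 line %d in %s: expected 9 tab-separated fields",
                 body[which(nf != 9)[1]], gff))
  gr <- rtracklayer::import(gff, format = "gff3")
  gr <- gr[!is.na(gr$type) & gr$type == "gene"]
  if (length(gr) == 0)
    return(data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) stop("GFF3 gene features must carry ID= attributes")
  data.frame(id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Combine shortest-distance and classifier rankings into a candidate report
#'
#' Joins the two per-gene rankings of a QTL interval on identical gene sets
#' and aggregates them by Borda count: `combined_rank` is the ascending order
#' of `sd_rank + ml_rank`, ties broken by ascending gene ID. Evidence columns
#' (`is_deg`, `variant_class`) are surfaced for annotation review but are not
#' re-scored here: they already entered both component scores as weights.
#'
#' @param sd ranked table from [score_region()].
#' @param ml ranked table from [p_w()].
#' @param interval optional [parse_interval()] object attached as metadata.
#' @param profiles optional [build_profiles()] table used to fill the
#'   evidence columns; without it `variant_class` degrades to what `p_v`
#'   reveals (`both` / `one_region` / `none`).
#' @return data.frame of class `candidate_report`, sorted by `combined_rank`,
#'   with columns `gene`, `sd_w`, `sd_rank`, `p_w`, `ml_rank`, `is_deg`,
#'   `variant_class`, `combined_rank`.
#' @export
rank_candidates <- function(sd, ml, interval = NULL, profiles = NULL) {
  only_sd <- setdiff(sd$gene, ml$gene)
  only_ml <- setdiff(ml$gene, sd$gene)
  if (length(only_sd) > 0 || length(only_ml) > 0)
    stop("SD and ML rankings cover different gene sets; only in SD: {",
         paste(only_sd, collapse = ", "), "}; only in ML: {",
         paste(only_ml, collapse = ", "), "}")
  i <- match(sd$gene, ml$gene)
  out <- data.frame(gene = sd$gene, sd_w = sd$sd_w, sd_rank = sd$rank,
                    p_w = ml$p_w[i], ml_rank = ml$rank[i],
                    stringsAsFactors = FALSE)
  if (!is.null(profiles)) {
    j <- match(out$gene, profiles$gene)
    out$is_deg <- ifelse(is.na(j), FALSE, profiles$is_deg[j])
    out$variant_class <- ifelse(is.na(j), "none", variant_class(profiles)[j])
  } else {
    out$is_deg <- ml$p_d[i] == 1
    out$variant_class <- ifelse(ml$p_v[i] == 1, "both",
                                ifelse(ml$p_v[i] == 0.5, "one_region", "none"))
  }
  borda <- out$sd_rank + out$ml_rank
  out <- out[order(borda, out$gene), , drop = FALSE]
  out$combined_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "interval") <- interval
  class(out) <- c("candidate_report", "data.frame")
  out
}

#' Write / read a candidate report TSV
#'
#' @param report a `candidate_report` (or any data.frame).
#' @param path output path.
#' @return `path` invisibly (write); the report data.frame (read).
#' @export
write_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
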