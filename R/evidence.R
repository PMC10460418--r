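#' The 13 admitted major-effect variant terms
#'
#' SnpEff effect terms with a high probability of altering gene expression
#' and/or protein structure or length. Eleven terms count as coding-region
#' evidence, the two `*_UTR_variant` terms as UTR-region evidence.
#'
#' @format character vector of 13 SnpEff effect terms.
#' @export
ADMITTED_EFFECTS <- c(
  "conservative_inframe_deletion", "conservative_inframe_insertion",
  "disruptive_inframe_deletion", "disruptive_inframe_insertion",
  "frameshift_variant", "splice_acceptor_variant", "splice_donor_variant",
  "splice_region_variant", "start_lost", "stop_gained", "stop_lost",
  "5_prime_UTR_variant", "3_prime_UTR_variant")

UTR_EFFECTS <- c("5_prime_UTR_variant", "3_prime_UTR_variant")

#' Region class of an admitted effect term
#' @param effect character vector of admitted effect terms.
#' @return character vector, `"utr"` or `"coding"`.
#' @export
effect_region <- function(effect) {
  stopifnot(all(effect %in% ADMITTED_EFFECTS))
  ifelse(effect %in% UTR_EFFECTS, "utr", "coding")
}

#' Parse major-effect variant annotations from a SnpEff-annotated VCF
#'
#' Reads a VCF whose INFO column carries the SnpEff `ANN` field (pipe-delimited
#' subfields; effect term in subfield 2, gene ID in subfield 4; multiple
#' annotations comma-separated). Only annotations whose effect matches one of
#' the 13 admitted major-effect terms are kept. `&`-composite effects are
#' admitted if any component is admitted; the recorded effect is the first
#' admitted component in ANN order. Multi-transcript annotations collapse to
#' gene level downstream, so duplicates per gene are retained here.
#'
#' @param vcf path to a VCF (plain or bgzipped) with SnpEff `ANN` annotations.
#' @param gene_universe optional character vector; annotations on genes outside
#'   it are dropped with a message reporting the count.
#' @return data.frame with columns `gene`, `effect`, `region`.
#' @export
parse_snpeff_vcf <- function(vcf, gene_universe = NULL) {
  if (!file.exists(vcf)) stop("VCF not found: ", vcf)
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  if (nrow(v@fix) == 0)
    return(data.frame(gene = character(), effect = character(),
                      region = character(), stringsAsFactors = FALSE))
  ann <- vcfR::extract.info(v, element = "ANN")
  if (all(is.na(ann)))
    stop("no ANN field found on any VCF record; is this VCF SnpEff-annotated?")
  entries <- unlist(strsplit(ann[!is.na(ann)], ",", fixed = TRUE))
  fields <- strsplit(entries, "|", fixed = TRUE)
  short <- lengths(fields) < 4
  if (any(short)) {
    warning(sprintf("skipped %d unparseable ANN entr%s (fewer than 4 subfields)",
                    sum(short), if (sum(short) == 1) "y" else "ies"))
    fields <- fields[!short]
  }
  if (length(fields) == 0)
    return(data.frame(gene = character(), effect = character(),
                      region = character(), stringsAsFactors = FALSE))
  raw_effect <- vapply(fields, `[`, character(1), 2L)
  gene <- vapply(fields, `[`, character(1), 4L)
  # first admitted component of each (possibly &-composite) effect
  first_admitted <- function(e) {
    comps <- strsplit(e, "&", fixed = TRUE)[[1]]
    hit <- comps[comps %in% ADMITTED_EFFECTS]
    if (length(hit) > 0) hit[1] else NA_character_
  }
  effect <- vapply(raw_effect, first_admitted, character(1), USE.NAMES = FALSE)
  keep <- !is.na(effect) & nzchar(gene)
  out <- data.frame(gene = gene[keep], effect = effect[keep],
                    stringsAsFactors = FALSE)
  if (!is.null(gene_universe)) {
    outside <- !(out$gene %in% gene_universe)
    if (any(outside))
      message(sprintf("parse_snpeff_vcf: dropped %d annotation(s) on genes outside the universe",
                      sum(outside)))
    out <- out[!outside, , drop = FALSE]
  }
  out$region <- effect_region(out$effect)
  rownames(out) <- NULL
  out
}

#' Read a differential-expression table
#'
#' TSV with header `gene`, `log2fc`, `q`.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `gene`, `log2fc`, `q`.
#' @export
read_deg_table <- function(path) {
  if (!file.exists(path)) stop("DEG table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "q")
  if (!all(need %in% names(tab)))
    stop("DEG table must have columns: ", paste(need, collapse = ", "))
  tab[, need]
}

#' Call differentially expressed genes at an FDR threshold
#'
#' Returns the genes whose multiple-testing-adjusted q-value is strictly below
#' the threshold (default 0.05).
#'
#' @param table data.frame with columns `gene` and `q`.
#' @param q_threshold strict upper bound on q, in (0, 1].
#' @return character vector of DEG gene IDs.
#' @export
call_degs <- function(table, q_threshold = 0.05) {
  stopifnot(is.data.frame(table))
  if (!(q_threshold > 0 && q_threshold <= 1))
    stop("q_threshold must be in (0, 1]")
  if (nrow(table) == 0) return(character())
  bad <- which(table$q < 0 | table$q > 1 | !is.finite(table$q))
  if (length(bad) > 0)
    stop("q outside [0,1] for gene(s): ",
         paste(table$gene[bad], collapse = ", "))
  unique(as.character(table$gene[table$q < q_threshold]))
}

#' Build per-gene evidence profiles and P_d / P_v weights
#'
#' For every gene in the universe, aggregates DEG status and major-effect
#' variant region flags into the evidence weights used by both the
#' shortest-distance and the probability rankers:
#' `p_d` is 1 for a DEG and 0 otherwise; `p_v` is 1 when the gene carries
#' admitted variants in both the coding and the UTR region, 0.5 when in
#' exactly one region, and 0 otherwise.
#'
#' @param degs character vector of DEG gene IDs (e.g. from [call_degs()]).
#' @param variants data.frame from [parse_snpeff_vcf()].
#' @param universe character vector of gene IDs defining the profile rows.
#' @return data.frame with columns `gene`, `is_deg`, `has_coding_variant`,
#'   `has_utr_variant`, `p_d`, `p_v`, one row per universe gene.
#' @export
build_profiles <- function(degs, variants, universe) {
  universe <- as.character(universe)
  coding_genes <- unique(variants$gene[variants$region == "coding"])
  utr_genes <- unique(variants$gene[variants$region == "utr"])
  is_deg <- universe %in% degs
  has_coding <- universe %in% coding_genes
  has_utr <- universe %in% utr_genes
  data.frame(
    gene = universe,
    is_deg = is_deg,
    has_coding_variant = has_coding,
    has_utr_variant = has_utr,
    p_d = as.numeric(is_deg),
    p_v = ifelse(has_coding & has_utr, 1, ifelse(has_coding | has_utr, 0.5, 0)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Human-readable variant class of a profile row
#' @param profiles data.frame from [build_profiles()].
#' @return character vector: `"both"`, `"coding"`, `"utr"` or `"none"`.
#' @export
variant_class <- function(profiles) {
  ifelse(profiles$has_coding_variant & profiles$has_utr_variant, "both",
         ifelse(profiles$has_coding_variant, "coding",
                ifelse(profiles$has_utr_variant, "utr", "none")))
}
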