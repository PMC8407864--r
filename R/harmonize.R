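# Probe filtering/harmonization across 450k and EPIC arrays, and
# gene-interval -> probe mapping for candidate-set analyses.

ANNOTATION_COLS <- c("probe_id", "chr", "pos", "on_450k", "on_epic",
                     "is_control", "on_snp", "cross_hybridizing")
VALID_CHROMS <- c(as.character(1:22), "X", "Y")

check_annotation <- function(annotation) {
  miss <- setdiff(ANNOTATION_COLS, names(annotation))
  if (length(miss))
    em_stop(paste("annotation columns missing:", paste(miss, collapse = ", ")),
            "ewasmeta_annotation_error")
  if (anyDuplicated(annotation$probe_id))
    em_stop("probe_id values must be unique", "ewasmeta_annotation_error")
  bad <- setdiff(unique(as.character(annotation$chr)), VALID_CHROMS)
  if (length(bad))
    em_stop(paste("unknown chromosome label(s):", paste(bad, collapse = ", ")),
            "ewasmeta_annotation_error")
  invisible(annotation)
}

#' Filter probes for meta-analysis
#'
#' Retains probes that are present on both the 450k and EPIC arrays, are not
#' control/QC probes, do not overlap a SNP, are not cross-hybridizing and do
#' not lie on the sex chromosomes. Exclusion counts are reported per rule in
#' application order with no double counting (a probe failing several rules
#' is counted under the first).
#'
#' @param annotation data.frame with columns probe_id, chr, pos, on_450k,
#'   on_epic, is_control, on_snp, cross_hybridizing.
#' @return list with `retained` (character vector of probe ids),
#'   `exclusions` (named integer vector in rule order) and `n_input`.
#' @export
filter_probes <- function(annotation) {
  if (nrow(annotation) == 0) em_stop("annotation is empty", "ewasmeta_annotation_error")
  check_annotation(annotation)
  active <- rep(TRUE, nrow(annotation))
  rules <- list(
    not_common_both_arrays = !(as.logical(annotation$on_450k) & as.logical(annotation$on_epic)),
    control_probe = as.logical(annotation$is_control),
    snp_probe = as.logical(annotation$on_snp),
    cross_hybridizing = as.logical(annotation$cross_hybridizing),
    sex_chromosome = as.character(annotation$chr) %in% c("X", "Y")
  )
  exclusions <- integer(length(rules))
  names(exclusions) <- names(rules)
  for (r in names(rules)) {
    hit <- active & rules[[r]]
    exclusions[r] <- sum(hit)
    active <- active & !hit
  }
  retained <- annotation$probe_id[active]
  if (length(retained) == 0)
    em_warn("no probes retained after filtering", "ewasmeta_empty_result")
  list(retained = retained, exclusions = exclusions, n_input = nrow(annotation))
}

#' Map gene intervals to the probes they contain
#'
#' A probe belongs to a gene iff it lies on the same chromosome and its
#' position falls inside the gene's 1-based closed interval
#' (start <= pos <= end). A probe may map to several overlapping genes.
#' Coordinates are assumed to share a genome build (declared, not verified);
#' strand is ignored.
#'
#' @param genes data.frame with columns gene, chr, start, end.
#' @param annotation probe annotation table (see [filter_probes()]).
#' @return named list: gene symbol -> character vector of probe ids (possibly
#'   empty).
#' @export
map_genes_to_probes <- function(genes, annotation) {
  check_annotation(annotation)
  stopifnot(all(c("gene", "chr", "start", "end") %in% names(genes)))
  gchr <- sub("^chr", "", as.character(genes$chr))
  bad <- setdiff(unique(gchr), VALID_CHROMS)
  if (length(bad))
    em_stop(paste("unknown chromosome label(s) in gene table:",
                  paste(bad, collapse = ", ")), "ewasmeta_annotation_error")
  if (any(genes$start > genes$end))
    em_stop("gene intervals must satisfy start <= end", "ewasmeta_annotation_error")
  gr_genes <- GenomicRanges::GRanges(gchr,
    IRanges::IRanges(start = genes$start, end = genes$end))
  gr_probes <- GenomicRanges::GRanges(as.character(annotation$chr),
    IRanges::IRanges(start = annotation$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_probes)
  out <- stats::setNames(vector("list", nrow(genes)), genes$gene)
  for (i in seq_len(nrow(genes))) out[[i]] <- character(0)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (length(qh)) {
    sp <- split(annotation$probe_id[sh], genes$gene[qh])
    out[names(sp)] <- lapply(sp, unique)
  }
  out
}

#' Simulate a probe annotation table
#'
#' Generates an annotation with independent Bernoulli exclusion flags and
#' positions spread over the autosomes (plus optional sex-chromosome
#' probes), for exercising the filtering and mapping machinery.
#'
#' @param n_probes number of probes.
#' @param seed integer seed.
#' @param p_450k_only,p_epic_only probabilities of being on only one array.
#' @param p_control,p_snp,p_cross probabilities of each exclusion flag.
#' @param p_sex probability of lying on chromosome X or Y.
#' @return annotation data.frame (see [filter_probes()]).
#' @export
simulate_probe_annotation <- function(n_probes, seed = 1L,
                                      p_450k_only = 0, p_epic_only = 0,
                                      p_control = 0, p_snp = 0, p_cross = 0,
                                      p_sex = 0) {
  withr::with_seed(as.integer(seed %% 2147483647), {
    chr <- sample(as.character(1:22), n_probes, replace = TRUE)
    if (p_sex > 0) {
      sexp <- stats::runif(n_probes) < p_sex
      chr[sexp] <- sample(c("X", "Y"), sum(sexp), replace = TRUE)
    }
    arr <- stats::runif(n_probes)
    on_450k <- rep(TRUE, n_probes); on_epic <- rep(TRUE, n_probes)
    on_epic[arr < p_450k_only] <- FALSE
    on_450k[arr >= p_450k_only & arr < p_450k_only + p_epic_only] <- FALSE
    data.frame(
      probe_id = probe_ids_for(n_probes),
      chr = chr,
      pos = sample.int(2e8, n_probes, replace = TRUE),
      on_450k = on_450k, on_epic = on_epic,
      is_control = stats::runif(n_probes) < p_control,
      on_snp = stats::runif(n_probes) < p_snp,
      cross_hybridizing = stats::runif(n_probes) < p_cross,
      stringsAsFactors = FALSE
    )
  })
}

#' Export probe positions as BED (0-based half-open)
#'
#' @param annotation probe annotation table.
#' @param path output BED path.
#' @return invisibly, the path.
#' @export
probes_to_bed <- function(annotation, path) {
  check_annotation(annotation)
  bed <- data.frame(chrom = paste0("chr", annotation$chr),
                    chromStart = annotation$pos - 1L,
                    chromEnd = annotation$pos,
                    name = annotation$probe_id)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write annotation and gene-interval tables
#'
#' Plain TSV round-trip helpers for the documented exchange formats.
#' @param path file path.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  a <- as.data.frame(data.table::fread(path, sep = "\t",
                                       colClasses = list(character = "chr")))
  check_annotation(a)
  a
}

#' @rdname read_annotation
#' @param annotation annotation table to write.
#' @export
write_annotation <- function(annotation, path) {
  check_annotation(annotation)
  data.table::fwrite(annotation, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname read_annotation
#' @export
read_gene_intervals <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
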