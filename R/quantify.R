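# Enhancer filtering, eRNA region derivation, RPM normalization and
# activity calling.

# Merge overlapping/touching intervals (tibble with start/end), per call.
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- numeric(0); me <- numeric(0)
  for (i in seq_along(start)) {
    if (length(me) && start[i] <= me[length(me)]) {
      me[length(me)] <- max(me[length(me)], end[i])
    } else {
      ms <- c(ms, start[i]); me <- c(me, end[i])
    }
  }
  list(start = ms, end = me)
}

#' Filter enhancers against annotated transcription
#'
#' An enhancer is removed when it overlaps (by at least 1 bp, half-open
#' coordinates) any exon, any gene body, or the windows extending
#' `extension` bp around any TSS or TES. This removes enhancers sitting in
#' introns, exons, promoters and terminators, keeping only intergenic loci
#' whose transcription can be attributed to the enhancer itself.
#'
#' @param enhancers Interval tibble (see [genomic_intervals()]).
#' @param genes Gene model tibble from [read_gtf()] or
#'   [simulate_annotation()].
#' @param extension Window half-width in bp around TSS and TES (default
#'   1000).
#' @return The retained subset of `enhancers`, input order preserved.
#'   Enhancers on chromosomes absent from the annotation are retained with
#'   a warning (no evidence of overlap).
#' @export
filter_enhancers <- function(enhancers, genes, extension = 1000) {
  enhancers <- genomic_intervals(enhancers)
  assert_scalar_number(extension, "extension", lo = 0)
  if (!nrow(enhancers)) return(enhancers)
  body_lo <- pmin(genes$tss, genes$tes)
  body_hi <- pmax(genes$tss, genes$tes) + 1 # half-open end
  elements <- bind_rows(
    tibble(chrom = genes$chrom, start = body_lo, end = body_hi),
    tibble(chrom = genes$chrom, start = pmax(0, genes$tss - extension),
           end = genes$tss + 1 + extension),
    tibble(chrom = genes$chrom, start = pmax(0, genes$tes - extension),
           end = genes$tes + 1 + extension),
    bind_rows(map2(genes$exons, genes$chrom, function(ex, ch) {
      if (!nrow(ex)) return(NULL)
      tibble(chrom = ch, start = ex$start, end = ex$end)
    }))
  )
  missing_chr <- setdiff(unique(enhancers$chrom), unique(elements$chrom))
  if (length(missing_chr)) {
    warn(sprintf("chromosome(s) %s absent from annotation; their enhancers are retained",
                 paste(missing_chr, collapse = ", ")))
  }
  keep <- rep(TRUE, nrow(enhancers))
  for (ch in intersect(unique(enhancers$chrom), unique(elements$chrom))) {
    el <- elements[elements$chrom == ch, ]
    m <- merge_intervals(el$start, el$end)
    idx <- which(enhancers$chrom == ch)
    # an enhancer [s, e) overlaps some merged element iff the last element
    # starting before e also ends after s
    pos <- findInterval(enhancers$end[idx] - 1e-9, m$start)
    hit <- pos >= 1 & m$end[pmax(pos, 1)] > enhancers$start[idx]
    keep[idx] <- !hit
  }
  enhancers[keep, ]
}

#' Derive fixed-width eRNA regions from retained enhancers
#'
#' Each candidate eRNA region is the `region_width` window (default 3 kb)
#' centered on the enhancer midpoint `floor((start + end) / 2)`. Regions
#' that would extend past the chromosome origin are shifted to start at 0
#' (keeping full width) and flagged `clipped`. The `erna_id` equals the
#' source enhancer id so count matrices indexed by enhancer carry over.
#'
#' @param enhancers Retained enhancer intervals.
#' @param region_width Region width in bp (default 3000).
#' @return Tibble with `erna_id`, `chrom`, `start`, `end`,
#'   `source_enhancer_id`, `midpoint`, `clipped`.
#' @export
derive_regions <- function(enhancers, region_width = 3000) {
  enhancers <- genomic_intervals(enhancers)
  if (!nrow(enhancers)) abort("no enhancers to derive regions from")
  assert_scalar_number(region_width, "region_width", lo = 2)
  mid <- floor((enhancers$start + enhancers$end) / 2)
  raw_start <- mid - floor(region_width / 2)
  clipped <- raw_start < 0
  start <- pmax(0, raw_start)
  tibble(
    erna_id = enhancers$id, chrom = enhancers$chrom,
    start = start, end = start + region_width,
    source_enhancer_id = enhancers$id, midpoint = mid, clipped = clipped
  )
}

#' Reads-per-million normalization
#'
#' `RPM = count * 1e6 / library_size`, where the library size is the
#' per-sample total of the full counts matrix when supplied. When
#' `library_sizes` is omitted, the column totals of `counts` itself are
#' used with a warning, since an eRNA submatrix underestimates the
#' sequencing depth.
#'
#' @param counts A `counts` matrix from [expr_matrix()].
#' @param library_sizes Optional named per-sample totals (e.g.
#'   `colSums(gene_counts) + colSums(erna_counts)`).
#' @return An RPM-tagged matrix of the same shape.
#' @export
rpm_normalize <- function(counts, library_sizes = NULL) {
  require_unit(counts, "counts")
  if (is.null(library_sizes)) {
    warn("no library sizes supplied; using column totals of the eRNA submatrix")
    library_sizes <- colSums(counts)
  }
  if (is.null(names(library_sizes)) ||
      !all(colnames(counts) %in% names(library_sizes))) {
    abort("library_sizes must be named and cover all samples")
  }
  lib <- library_sizes[colnames(counts)]
  if (any(lib <= 0)) {
    abort(sprintf("zero library size for sample %s", colnames(counts)[lib <= 0][1]))
  }
  rpm <- sweep(counts, 2L, lib / 1e6, "/")
  expr_matrix(rpm, "RPM")
}

#' Call active eRNAs from RPM values
#'
#' An eRNA is active when its RPM reaches `threshold` (default 1) in at
#' least one sample.
#'
#' @param rpm An RPM-tagged matrix.
#' @param threshold RPM threshold (inclusive).
#' @return Tibble with `erna_id`, `max_rpm`, `active`.
#' @export
call_active <- function(rpm, threshold = 1.0) {
  require_unit(rpm, "RPM")
  mx <- apply(rpm, 1L, max)
  calls <- tibble(erna_id = rownames(rpm), max_rpm = unname(mx),
                  active = unname(mx >= threshold))
  inform(sprintf("%d active / %d inactive eRNAs at RPM >= %g",
                 sum(calls$active), sum(!calls$active), threshold))
  calls
}
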