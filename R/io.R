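# Readers and writers for the external formats the pipeline touches.
# Everything downstream of these functions works in 0-based half-open
# genomic coordinates; GTF (1-based closed) is converted at this boundary.

pkg_header <- function(params = NULL) {
  v <- as.character(utils::packageVersion("ernascape"))
  extra <- if (length(params)) {
    paste0(" ", paste(names(params), unlist(params), sep = "=", collapse = " "))
  } else ""
  sprintf("# ernascape %s%s", v, extra)
}

#' Validate a table of genomic intervals
#'
#' Intervals are tibbles with columns `chrom`, `start`, `end`, `id` in
#' 0-based half-open coordinates. `end > start`, `start >= 0`, and ids must
#' be unique.
#'
#' @param x A data frame with columns `chrom`, `start`, `end` and optionally
#'   `id` (auto-generated as `"chrom:start-end"` when absent).
#' @return A validated tibble of intervals.
#' @export
genomic_intervals <- function(x) {
  x <- as_tibble(x)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) abort("intervals need columns chrom, start, end")
  if (!("id" %in% names(x))) {
    x$id <- sprintf("%s:%d-%d", x$chrom, as.integer(x$start), as.integer(x$end))
  }
  x <- select(x, "chrom", "start", "end", "id", dplyr::everything())
  x$start <- as.numeric(x$start); x$end <- as.numeric(x$end)
  if (any(x$start < 0)) abort("interval start must be >= 0")
  bad <- which(x$end <= x$start)
  if (length(bad)) {
    abort(sprintf("interval %s has end <= start (%d <= %d)",
                  x$id[bad[1]], as.integer(x$end[bad[1]]), as.integer(x$start[bad[1]])))
  }
  if (anyDuplicated(x$id)) abort("interval ids must be unique")
  x
}

#' Read / write BED intervals
#'
#' BED's native 0-based half-open coordinates are preserved unchanged. With
#' fewer than four columns, ids are generated as `"chrom:start-end"`.
#'
#' @param path Path to a BED3/BED6 file.
#' @return `read_bed()`: a tibble of intervals (`chrom`, `start`, `end`, `id`).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(genomic_intervals(tibble(chrom = character(), start = numeric(),
                                    end = numeric(), id = character())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L) abort(sprintf("malformed BED line %d: fewer than 3 columns", i))
    s <- suppressWarnings(as.numeric(p[2])); e <- suppressWarnings(as.numeric(p[3]))
    if (is.na(s) || is.na(e)) abort(sprintf("malformed BED line %d: non-numeric coordinates", i))
    if (e <= s) abort(sprintf("malformed BED line %d: start >= end (%s >= %s)", i, p[2], p[3]))
  }
  chrom <- map_chr(parts, 1L)
  start <- as.numeric(map_chr(parts, 2L))
  end <- as.numeric(map_chr(parts, 3L))
  id <- map_chr(parts, function(p) if (length(p) >= 4L && nzchar(p[4])) p[4] else NA_character_)
  missing_id <- is.na(id)
  id[missing_id] <- sprintf("%s:%d-%d", chrom[missing_id],
                            as.integer(start[missing_id]), as.integer(end[missing_id]))
  genomic_intervals(tibble(chrom = chrom, start = start, end = end, id = id))
}

#' @rdname read_bed
#' @param intervals A tibble of intervals as returned by [read_bed()].
#' @export
write_bed <- function(intervals, path) {
  intervals <- genomic_intervals(intervals)
  lines <- sprintf("%s\t%d\t%d\t%s", intervals$chrom,
                   as.integer(intervals$start), as.integer(intervals$end), intervals$id)
  writeLines(lines, path)
  invisible(path)
}

# ---- GTF --------------------------------------------------------------------

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(sprintf('%s "[^"]*"', key), attrs))
  ifelse(lengths(regmatches(attrs, gregexpr(sprintf('%s "[^"]*"', key), attrs))) > 0,
         sub(sprintf('^%s "([^"]*)"$', key), "\\1", m), NA_character_)
}

#' Read / write gene models from GTF
#'
#' GTF coordinates (1-based, closed) are converted to the internal 0-based
#' half-open convention. The transcription start site (`tss`) is the
#' strand-aware 5' end: for `+` genes `tss = start - 1`, for `-` genes
#' `tss = end - 1` (both 0-based positions). Exon records are grouped by
#' `gene_id` into a list column of 0-based half-open intervals.
#'
#' @param path Path to a GTF file with `gene` and/or `exon` records.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `tss`, `tes`
#'   and list column `exons`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) abort("GTF file has no records")
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 9L)) {
    abort(sprintf("malformed GTF line %d: fewer than 9 fields", which(lengths(f) < 9L)[1]))
  }
  rec <- tibble(
    chrom = map_chr(f, 1L), feature = map_chr(f, 3L),
    start = as.numeric(map_chr(f, 4L)), end = as.numeric(map_chr(f, 5L)),
    strand = map_chr(f, 7L), attrs = map_chr(f, 9L)
  )
  rec$gene_id <- gtf_attr(rec$attrs, "gene_id")
  if (anyNA(rec$gene_id)) {
    abort(sprintf("GTF record %d lacks a gene_id attribute", which(is.na(rec$gene_id))[1]))
  }
  if (!all(rec$strand %in% c("+", "-"))) {
    abort(sprintf("unknown strand %s in GTF", rec$strand[!rec$strand %in% c("+", "-")][1]))
  }
  rec <- filter(rec, .data$feature %in% c("gene", "transcript", "exon"))
  gene_extent <- rec |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              start = min(.data$start), end = max(.data$end), .groups = "drop")
  exon_rec <- filter(rec, .data$feature == "exon")
  exon_list <- split(
    tibble(start = exon_rec$start - 1, end = exon_rec$end,
           id = sprintf("%s:exon%d", exon_rec$gene_id,
                        stats::ave(exon_rec$start, exon_rec$gene_id, FUN = seq_along))),
    exon_rec$gene_id
  )
  out <- mutate(gene_extent,
    tss = ifelse(.data$strand == "+", .data$start - 1, .data$end - 1),
    tes = ifelse(.data$strand == "+", .data$end - 1, .data$start - 1),
    exons = unname(map(.data$gene_id, function(g) {
      ex <- exon_list[[g]]
      if (is.null(ex)) tibble(start = numeric(), end = numeric(), id = character()) else as_tibble(ex)
    }))
  ) |>
    select("gene_id", "chrom", "strand", "tss", "tes", "exons")
  validate_genes(out)
}

validate_genes <- function(genes) {
  genes <- as_tibble(genes)
  if (any(genes$tss == genes$tes)) abort("gene with tss == tes")
  neg <- genes$strand == "-"
  if (any(genes$tss[neg] <= genes$tes[neg])) abort("minus-strand gene must have tss > tes")
  if (any(genes$tss[!neg] >= genes$tes[!neg])) abort("plus-strand gene must have tss < tes")
  lo <- pmin(genes$tss, genes$tes); hi <- pmax(genes$tss, genes$tes)
  ok <- map_int(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    if (!nrow(ex)) return(1L)
    as.integer(all(ex$start >= lo[i] & ex$end <= hi[i] + 1))
  })
  if (any(ok == 0L)) abort(sprintf("gene %s has exons outside its span", genes$gene_id[ok == 0L][1]))
  genes
}

#' @rdname read_gtf
#' @param genes A gene tibble as returned by [read_gtf()].
#' @export
write_gtf <- function(genes, path) {
  genes <- validate_genes(genes)
  lines <- unlist(map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    lo <- min(g$tss, g$tes); hi <- max(g$tss, g$tes)
    attr_str <- sprintf('gene_id "%s";', g$gene_id)
    gene_line <- sprintf("%s\ternascape\tgene\t%d\t%d\t.\t%s\t.\t%s",
                         g$chrom, as.integer(lo + 1), as.integer(hi + 1), g$strand, attr_str)
    ex <- g$exons[[1]]
    exon_lines <- if (nrow(ex)) {
      sprintf("%s\ternascape\texon\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, as.integer(ex$start + 1), as.integer(ex$end), g$strand, attr_str)
    } else character()
    c(gene_line, exon_lines)
  }))
  writeLines(lines, path)
  invisible(path)
}

# ---- GMT --------------------------------------------------------------------

#' Read / write gene set collections (GMT)
#'
#' Gene sets are named lists of character vectors. Duplicate members within
#' a set are collapsed; empty sets are an error.
#'
#' @param path Path to a GMT file (set name, description, members...).
#' @return `read_gmt()`: a named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    p <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(p) < 3L) abort(sprintf("GMT line %d: empty gene set '%s'", i, p[1]))
    members <- unique(p[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) abort(sprintf("GMT line %d: empty gene set '%s'", i, p[1]))
    sets[[p[1]]] <- members
  }
  validate_gene_sets(sets)
}

validate_gene_sets <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("gene sets must be a named list")
  }
  if (any(lengths(sets) == 0L)) abort("gene sets must be non-empty")
  lapply(sets, unique)
}

#' @rdname read_gmt
#' @param sets A named list of gene-id vectors.
#' @export
write_gmt <- function(sets, path) {
  sets <- validate_gene_sets(sets)
  lines <- map_chr(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

# ---- expression matrices ----------------------------------------------------

#' Read / write expression matrices (TSV)
#'
#' Tab-separated, first column feature ids, header row of sample ids.
#' Leading `#` comment lines are skipped on read and a versioned comment
#' header is written out.
#'
#' @param path Path to the TSV file.
#' @param unit Unit tag for the loaded values (see [expr_matrix()]).
#' @return `read_matrix()`: a unit-tagged numeric matrix.
#' @export
read_matrix <- function(path, unit = c("counts", "RPM", "log2")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, colClasses = "character")
  if (!ncol(df) || nrow(df) == 0L) abort("empty matrix file")
  ids <- df[[1]]
  if (anyDuplicated(ids)) abort("duplicate feature ids in matrix")
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) abort(sprintf("duplicate sample id: %s", samples[duplicated(samples)][1]))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | !nzchar(trimws(vals)), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("non-numeric cell at feature '%s', sample '%s'",
                  ids[bad[1, 1]], samples[bad[1, 2]]))
  }
  dimnames(num) <- list(ids, samples)
  expr_matrix(num, unit)
}

#' @rdname read_matrix
#' @param x A unit-tagged matrix from [expr_matrix()].
#' @param params Optional named list recorded in the comment header.
#' @export
write_matrix <- function(x, path, params = NULL) {
  unit <- expr_unit(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(pkg_header(c(list(unit = unit), params)), con)
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- clinical tables --------------------------------------------------------

#' Read / write clinical survival tables
#'
#' Requires columns `sample_id`, `time` (months), `event` (0/1); any further
#' columns are carried along as covariates. Rows with `time < 1` month are
#' flagged in the logical `excluded` column for downstream filtering, the
#' convention used when short-survivors are removed for model stability.
#'
#' @param path Path to the TSV file.
#' @return A validated clinical tibble with an `excluded` flag column.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE)
  validate_clinical(as_tibble(df))
}

#' @rdname read_clinical
#' @param clinical A clinical tibble.
#' @export
validate_clinical <- function(clinical) {
  clinical <- as_tibble(clinical)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(clinical))) {
    abort("clinical table needs columns sample_id, time, event")
  }
  if (anyDuplicated(clinical$sample_id)) {
    abort(sprintf("duplicate sample_id: %s",
                  clinical$sample_id[duplicated(clinical$sample_id)][1]))
  }
  if (!is.numeric(clinical$time) || any(is.na(clinical$time)) || any(clinical$time <= 0)) {
    abort("survival time must be positive and non-missing")
  }
  if (!all(clinical$event %in% c(0, 1))) abort("event must be 0/1")
  clinical$excluded <- clinical$time < 1
  clinical
}

#' @rdname read_clinical
#' @export
write_clinical <- function(clinical, path) {
  clinical <- validate_clinical(clinical)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(pkg_header(), con)
  utils::write.table(select(clinical, -"excluded"), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Apply the short-survivor exclusion and report how many rows were dropped.
apply_exclusions <- function(clinical) {
  clinical <- validate_clinical(clinical)
  n_drop <- sum(clinical$excluded)
  if (n_drop > 0) inform(sprintf("excluding %d sample(s) with survival time < 1 month", n_drop))
  filter(clinical, !.data$excluded)
}
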