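# Strand codes follow the STAR SJ.out.tab convention: 0 = unknown, 1 = "+", 2 = "-".
.strand_codes <- c(unknown = 0L, `+` = 1L, `-` = 2L)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Construct a splice-junction table
#'
#' A junction table is one sample's worth of splice-loci output: one row per
#' junction with 1-based inclusive intron coordinates, a strand code
#' (0 unknown, 1 plus, 2 minus), splice-motif code, annotation flag, and
#' unique/multi-mapping read counts with the maximum spliced-alignment
#' overhang. Duplicate (chrom, intron_start, intron_end, strand) keys are
#' rejected.
#'
#' @param df data.frame with columns `chrom`, `intron_start`, `intron_end`,
#'   `strand`, `motif`, `annotated`, `unique_reads`, `multi_reads`,
#'   `max_overhang`.
#' @param sample_id sample label attached to the table.
#' @return A `junction_table` (data.frame subclass with a `sample_id`
#'   attribute).
#' @export
junction_table <- function(df, sample_id = "sample") {
  req <- c("chrom", "intron_start", "intron_end", "strand", "motif",
           "annotated", "unique_reads", "multi_reads", "max_overhang")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    .stopf("junction table missing columns: %s", paste(missing_cols, collapse = ", "))
  df <- df[, req, drop = FALSE]
  int_cols <- setdiff(req, "chrom")
  for (cl in int_cols) {
    v <- df[[cl]]
    if (any(!is.finite(v)) || any(v != round(v)))
      .stopf("column '%s' must be integer-valued", cl)
    df[[cl]] <- as.integer(round(v))
  }
  df$chrom <- as.character(df$chrom)
  if (any(df$intron_start > df$intron_end))
    .stopf("intron_start must be <= intron_end")
  if (any(df$intron_start < 1))
    .stopf("intron coordinates must be positive (1-based)")
  if (any(df$unique_reads < 0) || any(df$multi_reads < 0) || any(df$max_overhang < 0))
    .stopf("read counts and overhang must be non-negative")
  if (!all(df$strand %in% 0:2))
    .stopf("strand code must be 0 (unknown), 1 (+) or 2 (-)")
  if (!all(df$motif %in% 0:6))
    .stopf("motif code must be in 0..6")
  if (!all(df$annotated %in% 0:1))
    .stopf("annotated flag must be 0 or 1")
  key <- paste(df$chrom, df$intron_start, df$intron_end, df$strand)
  if (anyDuplicated(key))
    .stopf("duplicate junction key(s): %s", paste(unique(key[duplicated(key)]), collapse = "; "))
  rownames(df) <- NULL
  structure(df, sample_id = sample_id, class = c("junction_table", "data.frame"))
}

#' Read a STAR-style SJ.out.tab splice-junction file
#'
#' Parses the 9-column tab-separated splice-loci dialect written by the STAR
#' aligner: chromosome, intron start (1-based, first base of intron), intron
#' end (1-based, inclusive), strand code, intron motif code, annotation flag,
#' unique-mapping read count, multi-mapping read count, maximum overhang.
#'
#' @param path path to the SJ.out.tab file.
#' @param sample_id sample label; defaults to the file name stripped of its
#'   extension.
#' @return A [junction_table()].
#' @export
read_sj_tab <- function(path, sample_id = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    empty <- data.frame(chrom = character(), intron_start = integer(),
                        intron_end = integer(), strand = integer(),
                        motif = integer(), annotated = integer(),
                        unique_reads = integer(), multi_reads = integer(),
                        max_overhang = integer())
    return(junction_table(empty, sample_id = sample_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    .stopf("%s: line %d has %d fields, expected 9", path, which(nf != 9L)[1], nf[nf != 9L][1])
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, 2:9, drop = FALSE], 2, as.numeric))
  if (is.null(dim(num))) num <- matrix(num, nrow = 1)
  if (any(is.na(num)))
    .stopf("%s: non-numeric field at line %d", path, which(rowSums(is.na(num)) > 0)[1])
  df <- data.frame(chrom = m[, 1], intron_start = num[, 1], intron_end = num[, 2],
                   strand = num[, 3], motif = num[, 4], annotated = num[, 5],
                   unique_reads = num[, 6], multi_reads = num[, 7],
                   max_overhang = num[, 8], stringsAsFactors = FALSE)
  junction_table(df, sample_id = sample_id)
}

#' Write a junction table as SJ.out.tab
#'
#' Inverse of [read_sj_tab()]; `write_sj_tab(read_sj_tab(f), g)` leaves `g`
#' byte-identical to `f`.
#'
#' @param table a [junction_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sj_tab <- function(table, path) {
  stopifnot(inherits(table, "junction_table"))
  lines <- sprintf("%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%d",
                   table$chrom, table$intron_start, table$intron_end,
                   table$strand, table$motif, table$annotated,
                   table$unique_reads, table$multi_reads, table$max_overhang)
  writeLines(lines, path)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (set name -> member genes).
#' @param descriptions optional named character vector of set descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) > 0 && (is.null(names(sets)) || any(!nzchar(names(sets)))))
    .stopf("every gene set must be named")
  if (anyDuplicated(names(sets)))
    .stopf("duplicate gene set names")
  sets <- lapply(sets, as.character)
  if (any(lengths(sets) == 0))
    .stopf("empty gene sets are not allowed")
  for (nm in names(sets)) {
    if (anyDuplicated(sets[[nm]])) {
      warning(sprintf("set '%s': duplicate member labels de-duplicated", nm), call. = FALSE)
      sets[[nm]] <- unique(sets[[nm]])
    }
  }
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  } else {
    descriptions <- descriptions[names(sets)]
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
names.gene_set_collection <- function(x) names(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  if (length(x$sets) == 0) cat("gene_set_collection with 0 sets\n")
  else cat(sprintf("gene_set_collection with %d sets (sizes %d..%d)\n",
                   length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' GMT is the MSigDB tab-separated format: set name, description, then member
#' genes. Duplicate members within a set are de-duplicated with a warning;
#' lines with fewer than three fields (i.e. sets with no members) are an
#' error.
#'
#' @param path path to the .gmt file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    .stopf("%s: line %d has %d fields; GMT lines need name, description and at least one gene",
           path, which(nf < 3L)[1], nf[nf < 3L][1])
  nms <- vapply(fields, `[[`, character(1), 1)
  desc <- setNames(vapply(fields, `[[`, character(1), 2), nms)
  sets <- setNames(lapply(fields, function(f) f[-(1:2)]), nms)
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection as GMT
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a count matrix with a sample-to-group design
#'
#' @param counts non-negative integer matrix, genes in rows (rownames are gene
#'   ids), samples in columns (colnames are sample ids).
#' @param design named character vector mapping every sample id to its group
#'   label.
#' @return A `count_matrix`.
#' @export
count_matrix <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .stopf("counts must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    .stopf("gene and sample ids must be unique")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    .stopf("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  design <- setNames(as.character(design), names(design))
  absent <- setdiff(colnames(counts), names(design))
  if (length(absent) > 0)
    .stopf("sample(s) missing from design: %s", paste(absent, collapse = ", "))
  design <- design[colnames(counts)]
  structure(list(counts = counts, design = design), class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples; groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s (n=%d)", names(table(x$design)), table(x$design)),
                    collapse = ", ")))
  invisible(x)
}

#' Read a gene-count TSV with its design table
#'
#' The counts file is tab-separated with gene ids in the first column and a
#' header row of sample ids; the design file is a two-column CSV
#' (`sample,group`). Non-integer counts and samples absent from the design are
#' errors.
#'
#' @param path counts TSV path.
#' @param design_path design CSV path.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, design_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) .stopf("%s: counts TSV needs a gene column plus >=1 sample", path)
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) .stopf("%s: non-numeric count entries", path)
  if (any(m != round(m)))
    .stopf("%s: non-integer count (first offending value %s)", path, m[m != round(m)][1])
  rownames(m) <- genes
  des <- utils::read.csv(design_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(des)))
    .stopf("%s: design CSV must have columns sample,group", design_path)
  count_matrix(m, setNames(des$group, des$sample))
}

#' Write a count matrix and its design
#' @param m a [count_matrix()].
#' @param path counts TSV path.
#' @param design_path design CSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, design_path) {
  stopifnot(inherits(m, "count_matrix"))
  df <- data.frame(gene = rownames(m$counts), m$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(data.frame(sample = names(m$design), group = unname(m$design)),
                   design_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a survival cohort
#'
#' @param sample_ids sample labels.
#' @param time non-negative follow-up times (study units).
#' @param event event indicator: 1 = event observed, 0 = censored.
#' @param expression optional genes x samples expression matrix whose columns
#'   follow `sample_ids` order.
#' @return A `survival_cohort`.
#' @export
survival_cohort <- function(sample_ids, time, event, expression = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) .stopf("duplicate sample ids in cohort")
  if (length(time) != length(sample_ids) || length(event) != length(sample_ids))
    .stopf("time and event must match sample_ids in length")
  if (any(!is.finite(time)) || any(time < 0)) .stopf("times must be non-negative")
  if (!all(event %in% c(0, 1))) .stopf("event indicator must be 0 or 1")
  if (!is.null(expression)) {
    expression <- as.matrix(expression)
    if (ncol(expression) != length(sample_ids) ||
        !identical(colnames(expression), sample_ids))
      .stopf("expression columns must match sample_ids exactly (same order)")
  }
  structure(list(sample_ids = sample_ids, time = as.numeric(time),
                 event = as.integer(event), expression = expression),
            class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("survival_cohort: %d samples, %d events (%.0f%% censored)%s\n",
              length(x$sample_ids), sum(x$event),
              100 * mean(x$event == 0),
              if (is.null(x$expression)) "" else
                sprintf(", expression %d genes", nrow(x$expression))))
  invisible(x)
}

#' Read a survival cohort CSV (sample,time,event) with optional expression TSV
#'
#' @param path cohort CSV with header `sample,time,event`.
#' @param expr_path optional expression TSV (genes x samples, first column
#'   gene id); its samples are reordered to the cohort order and must cover
#'   every cohort sample.
#' @return A [survival_cohort()].
#' @export
read_survival <- function(path, expr_path = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "time", "event") %in% names(tab)))
    .stopf("%s: cohort CSV must have columns sample,time,event", path)
  expr <- NULL
  if (!is.null(expr_path)) {
    e <- utils::read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
    expr <- as.matrix(e[, -1, drop = FALSE])
    rownames(expr) <- as.character(e[[1]])
    absent <- setdiff(tab$sample, colnames(expr))
    if (length(absent) > 0)
      .stopf("%s: expression missing cohort sample(s): %s", expr_path,
             paste(absent, collapse = ", "))
    expr <- expr[, tab$sample, drop = FALSE]
  }
  survival_cohort(tab$sample, tab$time, tab$event, expr)
}

#' Write a cohort's sample/time/event table
#' @param cohort a [survival_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(cohort, path) {
  stopifnot(inherits(cohort, "survival_cohort"))
  utils::write.csv(data.frame(sample = cohort$sample_ids, time = cohort$time,
                              event = cohort$event),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a results table as TSV with deterministic column order
#'
#' Numeric columns are serialized with 15 significant digits so that
#' `read_results(write_results(x))` reproduces values to better than 1e-12
#' relative error.
#'
#' @param table a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  for (cl in names(out)) {
    if (is.numeric(out[[cl]]) && !is.integer(out[[cl]]))
      out[[cl]] <- formatC(out[[cl]], digits = 15, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results TSV written by [write_results()]
#' @param path input path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
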