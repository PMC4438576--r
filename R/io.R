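#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix of log2 intensities with
#' feature identifiers as row names (probesets or gene symbols), sample
#' identifiers as column names, and a `level` attribute recording whether
#' rows are probesets or genes.  All downstream functions operate on this
#' representation.
#'
#' @param values numeric matrix, features x samples, finite log2 intensities.
#' @param level `"gene"` or `"probeset"`. At gene level duplicate feature
#'   identifiers are an error; at probeset level they are too (probeset ids
#'   are unique on the array).
#' @return the matrix with a `level` attribute, invisibly validated.
#' @export
expression_matrix <- function(values, level = c("gene", "probeset")) {
  level <- match.arg(level)
  abort_if(!is.matrix(values) || !is.numeric(values),
           "`values` must be a numeric matrix")
  abort_if(is.null(rownames(values)) || is.null(colnames(values)),
           "expression matrix needs feature row names and sample column names")
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  abort_if(length(dup_f) > 0L, "duplicate feature ids: ",
           paste(dup_f, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  abort_if(length(dup_s) > 0L, "duplicate sample ids: ",
           paste(dup_s, collapse = ", "))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  abort_if(nrow(bad) > 0L, sprintf(
    "non-finite expression value at feature '%s', sample '%s'",
    rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]]))
  attr(values, "level") <- level
  values
}

#' @rdname expression_matrix
#' @param x object to query.
#' @export
expr_level <- function(x) attr(x, "level") %||% "gene"

#' Read an expression matrix from TSV or GCT
#'
#' The TSV dialect is a header row of sample identifiers (first column
#' `feature_id`) followed by one row per feature.  The GCT dialect is
#' version 1.2 only: `#1.2`, a `rows<TAB>cols` line, then a header with
#' `Name` and `Description` columns.  Descriptions are preserved in the
#' `"descriptions"` attribute but otherwise unused.  Missing or non-numeric
#' cells are hard errors (normalized array output contains none).
#'
#' @param path file path.
#' @param format `"auto"` (sniff the first line), `"tsv"` or `"gct"`.
#' @param level feature level of the stored matrix, see [expression_matrix()].
#' @return an expression matrix.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct"),
                            level = c("gene", "probeset")) {
  format <- match.arg(format)
  level <- match.arg(level)
  abort_if(!file.exists(path), "no such file: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "#1.2")) "gct" else "tsv"
  }
  if (format == "gct") {
    lines <- readLines(path)
    abort_if(length(lines) < 3L || !identical(lines[[1L]], "#1.2"),
             "not a GCT 1.2 file: ", path)
    dims <- as.integer(strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]])
    body <- parse_delim_matrix(lines[-(1:2)], path, n_id_cols = 2L)
    abort_if(nrow(body$values) != dims[[1L]] || ncol(body$values) != dims[[2L]],
             "GCT dimension line disagrees with the data block")
    m <- expression_matrix(body$values, level = level)
    attr(m, "descriptions") <- body$descriptions
    m
  } else {
    body <- parse_delim_matrix(readLines(path), path, n_id_cols = 1L)
    expression_matrix(body$values, level = level)
  }
}

# Shared TSV/GCT body parser: first n_id_cols columns are identifiers,
# the rest numeric.  Errors carry row/column coordinates.
parse_delim_matrix <- function(lines, path, n_id_cols) {
  abort_if(length(lines) < 1L, "empty expression file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  sample_ids <- header[-seq_len(n_id_cols)]
  abort_if(length(sample_ids) < 1L, "no sample columns in ", path)
  dup <- unique(sample_ids[duplicated(sample_ids)])
  abort_if(length(dup) > 0L, "duplicate sample ids in ", path, ": ",
           paste(dup, collapse = ", "))
  rows <- fields[-1L]
  abort_if(length(rows) < 1L, "no feature rows in ", path)
  nf <- lengths(rows)
  abort_if(any(nf != length(header)), sprintf(
    "ragged row %d in %s: %d fields, expected %d",
    which(nf != length(header))[1L] + 1L, path,
    nf[nf != length(header)][1L], length(header)))
  ids <- vapply(rows, `[[`, "", 1L)
  dup <- unique(ids[duplicated(ids)])
  abort_if(length(dup) > 0L, "duplicate feature ids in ", path, ": ",
           paste(dup, collapse = ", "))
  raw <- t(vapply(rows, function(f) f[-seq_len(n_id_cols)],
                  character(length(sample_ids))))
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  abort_if(nrow(bad) > 0L, sprintf(
    "non-numeric cell '%s' at feature '%s', sample '%s' in %s",
    raw[bad[1L, , drop = FALSE]], ids[bad[1L, 1L]],
    sample_ids[bad[1L, 2L]], path))
  dimnames(vals) <- list(ids, sample_ids)
  desc <- if (n_id_cols == 2L) {
    stats::setNames(vapply(rows, `[[`, "", 2L), ids)
  }
  list(values = vals, descriptions = desc)
}

#' Write an expression matrix to TSV or GCT 1.2
#'
#' Values are serialized at full double precision so that read/write
#' round-trips are the identity both in memory and on disk.
#'
#' @param mat expression matrix.
#' @param path output path.
#' @param format `"tsv"` or `"gct"`.
#' @export
write_expression <- function(mat, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  vals <- apply(mat, 2L, num_chr)
  if (nrow(mat) == 1L) vals <- matrix(vals, nrow = 1L)
  if (format == "tsv") {
    lines <- c(paste(c("feature_id", colnames(mat)), collapse = "\t"),
               paste(rownames(mat), apply(vals, 1L, paste, collapse = "\t"),
                     sep = "\t"))
  } else {
    desc <- attr(mat, "descriptions") %||%
      stats::setNames(rep("na", nrow(mat)), rownames(mat))
    lines <- c("#1.2",
               paste(nrow(mat), ncol(mat), sep = "\t"),
               paste(c("Name", "Description", colnames(mat)), collapse = "\t"),
               paste(rownames(mat), desc[rownames(mat)],
                     apply(vals, 1L, paste, collapse = "\t"), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' Tab-delimited with header columns `sample_id`, `group`, `is_target`.
#' Exactly one group must be flagged as the target cohort, and the flag must
#' cover all of that group's members.
#'
#' @param path file path.
#' @return data frame with columns `sample_id`, `group`, `is_target`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  abort_if(!all(c("sample_id", "group", "is_target") %in% names(df)),
           "sample sheet needs columns sample_id, group, is_target")
  df$is_target <- as.logical(df$is_target)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet a sample-sheet data frame.
#' @param mat optional expression matrix whose samples must match the sheet.
#' @export
validate_sample_sheet <- function(sheet, mat = NULL) {
  dup <- unique(sheet$sample_id[duplicated(sheet$sample_id)])
  abort_if(length(dup) > 0L, "duplicate sample ids in sheet: ",
           paste(dup, collapse = ", "))
  tg <- unique(sheet$group[sheet$is_target])
  abort_if(length(tg) != 1L, "exactly one group must be the target cohort")
  abort_if(!all(sheet$is_target[sheet$group == tg]),
           "all members of the target group must be flagged is_target")
  if (!is.null(mat)) {
    missing <- setdiff(colnames(mat), sheet$sample_id)
    abort_if(length(missing) > 0L, "samples absent from sheet: ",
             paste(missing, collapse = ", "))
    extra <- setdiff(sheet$sample_id, colnames(mat))
    abort_if(length(extra) > 0L, "sheet samples absent from matrix: ",
             paste(extra, collapse = ", "))
  }
  sheet
}

#' Target group name of a sample sheet
#' @param sheet a validated sample sheet.
#' @export
target_group <- function(sheet) unique(sheet$group[sheet$is_target])

#' Read a gene-set collection from GMT
#'
#' Standard GMT dialect: one set per line, tab-separated `term`,
#' `description`, then member genes.  Duplicate members within a line are
#' dropped; fewer than three fields or a repeated term id is an error.
#'
#' @param path file path.
#' @return a named list of unique member-gene vectors with a `term_names`
#'   attribute (descriptions).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(gene_set_collection(list(), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  abort_if(length(short) > 0L,
           sprintf("GMT line %d has fewer than 3 fields in %s",
                   short[1L], path))
  ids <- vapply(fields, `[[`, "", 1L)
  dup <- unique(ids[duplicated(ids)])
  abort_if(length(dup) > 0L, "duplicate term ids in ", path, ": ",
           paste(dup, collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- ids
  gene_set_collection(sets, vapply(fields, `[[`, "", 2L))
}

#' @rdname read_gmt
#' @param sets named list of member-gene character vectors.
#' @param term_names character vector of descriptions, one per set.
#' @export
gene_set_collection <- function(sets, term_names = names(sets)) {
  abort_if(any(lengths(sets) == 0L), "gene sets must be non-empty")
  dup <- unique(names(sets)[duplicated(names(sets))])
  abort_if(length(dup) > 0L, "duplicate term ids: ", paste(dup, collapse = ", "))
  attr(sets, "term_names") <- stats::setNames(as.character(term_names),
                                              names(sets))
  class(sets) <- c("gene_set_collection", "list")
  sets
}

#' Write a gene-set collection as GMT
#' @param sets a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  nm <- attr(sets, "term_names") %||% stats::setNames(names(sets), names(sets))
  writeLines(vapply(names(sets), function(id) {
    paste(c(id, nm[[id]], sets[[id]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Read a probeset-to-gene map
#'
#' Two-column tab-delimited file with a header; first column probeset id,
#' second gene symbol.  Mapping is many-to-one.
#'
#' @param path file path.
#' @return named character vector, probeset id -> gene symbol.
#' @export
read_probeset_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  abort_if(ncol(df) < 2L, "probeset map needs two columns")
  dup <- unique(df[[1L]][duplicated(df[[1L]])])
  abort_if(length(dup) > 0L, "duplicate probeset ids in map: ",
           paste(dup, collapse = ", "))
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Read a drug-target map
#'
#' Tab-delimited with a header; first column gene symbol, second a
#' comma-separated list of therapeutic agents targeting that gene product.
#'
#' @param path file path.
#' @return named list of agent character vectors.
#' @export
read_drug_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  abort_if(ncol(df) < 2L, "drug map needs two columns")
  dup <- unique(df[[1L]][duplicated(df[[1L]])])
  abort_if(length(dup) > 0L, "duplicate gene symbols in drug map: ",
           paste(dup, collapse = ", "))
  agents <- strsplit(as.character(df[[2L]]), ",[ ]*")
  abort_if(any(lengths(agents) == 0L | !nzchar(vapply(agents, `[[`, "", 1L))),
           "empty agent list in drug map")
  stats::setNames(agents, as.character(df[[1L]]))
}

#' Write a drug-target map
#' @param map named list of agent vectors.
#' @param path output path.
#' @export
write_drug_map <- function(map, path) {
  writeLines(c("gene\tagents",
               paste(names(map),
                     vapply(map, paste, "", collapse = ", "), sep = "\t")),
             path)
  invisible(path)
}

#' Read a patient-characteristics table
#'
#' Tab-delimited with header columns `upn`, `ctnnb1_status`, `braf_status`,
#' `age_at_dx`.  An age of `-` (or empty) is missing; present ages must be
#' non-negative.
#'
#' @param path file path.
#' @return data frame of patient records.
#' @export
read_patient_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  abort_if(!all(c("upn", "age_at_dx") %in% names(df)),
           "patient table needs columns upn and age_at_dx")
  age <- df$age_at_dx
  age[age %in% c("-", "", "NA")] <- NA_character_
  df$age_at_dx <- as.numeric(age)
  abort_if(any(df$age_at_dx < 0, na.rm = TRUE), "negative age_at_dx")
  df
}

#' Median age at diagnosis of a patient cohort
#'
#' Median of the non-missing ages; for an even count, the mean of the two
#' central values.  All-missing ages are an error.
#'
#' @param records data frame with an `age_at_dx` column (years).
#' @return median age in years.
#' @export
cohort_median_age <- function(records) {
  age <- records$age_at_dx
  age <- age[!is.na(age)]
  abort_if(length(age) == 0L, "no non-missing ages in cohort")
  stats::median(age)
}
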