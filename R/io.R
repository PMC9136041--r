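# Strict tabular IO for the four artifact kinds the pipeline touches:
# wide abundance tables, sample metadata, metabolite annotation, and
# GMT pathway maps.  All readers validate hard and fail loudly; all
# writers emit UTF-8 with LF line endings and enough digits that a
# write/read round trip reproduces values exactly.

SYNDROME_LEVELS <- c("IPBS", "PQD", "PQS", "PST")

METADATA_NUMERIC <- c("age", "weight", "fasting_glucose", "tg", "tc", "ldl_c")
METADATA_YESNO <- c("hypertension", "diabetes")

.sep_for <- function(dialect) if (dialect == "tsv") "\t" else ","

.check_rectangular <- function(path, sep) {
  fields <- utils::count.fields(path, sep = sep, quote = "\"",
                                comment.char = "")
  if (anyNA(fields)) {
    stop("unbalanced quotes at line ", which(is.na(fields))[1], " of ", path)
  }
  bad <- which(fields != fields[1])
  if (length(bad)) {
    stop("ragged row in ", path, ": line ", bad[1] + 0L, " has ",
         fields[bad[1]], " fields, expected ", fields[1])
  }
  invisible(fields[1])
}

.read_table <- function(path, dialect) {
  sep <- .sep_for(dialect)
  .check_rectangular(path, sep)
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    check.names = FALSE, colClasses = "character",
                    comment.char = "", fileEncoding = "UTF-8",
                    na.strings = character(0), stringsAsFactors = FALSE)
}

.write_table <- function(df, path, dialect) {
  utils::write.table(df, path, sep = .sep_for(dialect),
                     quote = (dialect == "csv"), qmethod = "double",
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
}

# NA tokens accepted in numeric cells: empty string, NA, NaN (any case).
.is_na_token <- function(x) toupper(trimws(x)) %in% c("", "NA", "NAN")

.fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

.dup_msg <- function(ids, what) {
  d <- unique(ids[duplicated(ids)])
  if (length(d)) {
    stop("duplicate ", what, ": ", paste(utils::head(d, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a wide-format metabolite abundance table
#'
#' Reads a samples x metabolites table of non-negative peak-area
#' intensities.  The first column must be `sample_id`; every remaining
#' header cell is a metabolite identifier.  Cells must parse as
#' non-negative numbers or one of the missing-value tokens (empty cell,
#' `NA`, `NaN`, case-insensitive); any other content is an error, not a
#' missing value.
#'
#' @param path Path to a TSV or CSV file.
#' @param dialect `"tsv"` (default, recommended: metabolite names often
#'   contain commas) or `"csv"`.
#' @return A numeric matrix with sample ids as row names and metabolite
#'   ids as column names; missing cells are `NA`.  Row/column order is
#'   preserved from the file.
#' @export
read_abundance <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- .read_table(path, dialect)
  if (ncol(df) < 2 || colnames(df)[1] != "sample_id") {
    stop("abundance table must start with a 'sample_id' column")
  }
  sample_ids <- df[[1]]
  metabolite_ids <- colnames(df)[-1]
  .dup_msg(sample_ids, "sample_id")
  .dup_msg(metabolite_ids, "metabolite_id")
  raw <- as.matrix(df[, -1, drop = FALSE])
  na_mask <- .is_na_token(raw)
  num <- suppressWarnings(as.numeric(raw))
  bad <- !na_mask & is.na(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = FALSE)[1]
    rc <- arrayInd(idx, dim(raw))
    stop("non-numeric value ", dQuote(raw[idx]), " at sample ",
         sample_ids[rc[1]], ", metabolite ", metabolite_ids[rc[2]])
  }
  neg <- !na_mask & num < 0
  if (any(neg)) {
    idx <- which(neg)[1]
    rc <- arrayInd(idx, dim(raw))
    stop("negative intensity at sample ", sample_ids[rc[1]],
         ", metabolite ", metabolite_ids[rc[2]])
  }
  num[na_mask] <- NA_real_
  mat <- matrix(num, nrow = nrow(raw), ncol = ncol(raw),
                dimnames = list(sample_ids, metabolite_ids))
  mat
}

#' Write a wide-format metabolite abundance table
#'
#' Inverse of [read_abundance()]; numbers are printed with 17
#' significant digits so that `read_abundance(write_abundance(x))`
#' reproduces `x` exactly.
#'
#' @param mat Numeric matrix, samples in rows (row/column names are the
#'   identifiers); `NA` cells are written as `NA`.
#' @param path Output path.
#' @inheritParams read_abundance
#' @return `path`, invisibly.
#' @export
write_abundance <- function(mat, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (dialect == "tsv") .check_no_tabs(c(rownames(mat), colnames(mat)))
  chr <- apply(mat, 2, .fmt_num)
  if (!is.matrix(chr)) chr <- matrix(chr, nrow = nrow(mat))
  df <- data.frame(sample_id = rownames(mat), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", colnames(mat))
  .write_table(df, path, dialect)
  invisible(path)
}

.check_no_tabs <- function(ids) {
  bad <- grepl("[\t\n]", ids)
  if (any(bad)) {
    stop("identifier contains a tab or newline (unrepresentable in TSV): ",
         dQuote(ids[bad][1]))
  }
  invisible(TRUE)
}

#' Read a sample metadata table
#'
#' Requires `sample_id` and `syndrome` columns; the syndrome label is
#' matched case-insensitively against the closed set IPBS, PQD, PQS,
#' PST.  The optional clinical covariates are recognized by canonical
#' name: `age`, `weight`, `sex`, `hypertension`, `diabetes`,
#' `fasting_glucose`, `tg`, `tc`, `ldl_c`.
#'
#' @inheritParams read_abundance
#' @return A data.frame, one row per sample, with `syndrome` normalized
#'   to upper case, numeric covariates parsed, and `sex`/yes-no fields
#'   normalized to lower case.
#' @export
read_metadata <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- .read_table(path, dialect)
  need <- c("sample_id", "syndrome")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  .dup_msg(df$sample_id, "sample_id")
  validate_metadata(df)
}

#' Validate (and normalize) a metadata data.frame
#'
#' @param df data.frame with at least `sample_id` and `syndrome`.
#' @return The normalized data.frame.
#' @export
validate_metadata <- function(df) {
  syn <- toupper(trimws(as.character(df$syndrome)))
  bad <- !(syn %in% SYNDROME_LEVELS)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("unknown syndrome label ", dQuote(df$syndrome[i]),
         " for sample ", df$sample_id[i],
         " (expected one of ", paste(SYNDROME_LEVELS, collapse = ", "), ")")
  }
  df$syndrome <- syn
  for (col in intersect(METADATA_NUMERIC, colnames(df))) {
    x <- as.character(df[[col]])
    v <- suppressWarnings(as.numeric(x))
    bad <- !.is_na_token(x) & is.na(v)
    if (any(bad)) {
      stop("non-numeric ", col, " value ", dQuote(x[which(bad)[1]]),
           " for sample ", df$sample_id[which(bad)[1]])
    }
    v[.is_na_token(x)] <- NA_real_
    df[[col]] <- v
  }
  if ("sex" %in% colnames(df)) {
    s <- tolower(trimws(as.character(df$sex)))
    bad <- !(s %in% c("male", "female")) & !.is_na_token(s)
    if (any(bad)) {
      stop("sex must be male/female, got ", dQuote(df$sex[which(bad)[1]]))
    }
    s[.is_na_token(s)] <- NA_character_
    df$sex <- s
  }
  for (col in intersect(METADATA_YESNO, colnames(df))) {
    s <- tolower(trimws(as.character(df[[col]])))
    bad <- !(s %in% c("yes", "no")) & !.is_na_token(s)
    if (any(bad)) {
      stop(col, " must be yes/no, got ", dQuote(df[[col]][which(bad)[1]]))
    }
    s[.is_na_token(s)] <- NA_character_
    df[[col]] <- s
  }
  rownames(df) <- NULL
  df
}

#' Write a sample metadata table
#' @param df Metadata data.frame (see [read_metadata()]).
#' @inheritParams write_abundance
#' @return `path`, invisibly.
#' @export
write_metadata <- function(df, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  out <- df
  for (col in intersect(METADATA_NUMERIC, colnames(out))) {
    out[[col]] <- .fmt_num(out[[col]])
  }
  .write_table(out, path, dialect)
  invisible(path)
}

#' Read a metabolite annotation table
#'
#' Requires `metabolite_id` and a non-empty `primary_class` for every
#' row; `secondary_class` and `compound_key` (the pathway-compound
#' identifier, e.g. a KEGG compound id) are optional.
#'
#' @inheritParams read_abundance
#' @return A data.frame with one row per metabolite.
#' @export
read_annotation <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- .read_table(path, dialect)
  need <- c("metabolite_id", "primary_class")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  .dup_msg(df$metabolite_id, "metabolite_id")
  empty <- .is_na_token(df$primary_class)
  if (any(empty)) {
    stop("empty primary_class for metabolite ",
         df$metabolite_id[which(empty)[1]])
  }
  if ("compound_key" %in% colnames(df)) {
    df$compound_key[.is_na_token(df$compound_key)] <- NA_character_
  }
  rownames(df) <- NULL
  df
}

#' Write a metabolite annotation table
#' @param df Annotation data.frame (see [read_annotation()]).
#' @inheritParams write_abundance
#' @return `path`, invisibly.
#' @export
write_annotation <- function(df, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  .write_table(df, path, dialect)
  invisible(path)
}

#' Read a pathway map in GMT format
#'
#' One pathway per line: `pathway_id TAB pathway_name TAB member TAB
#' member ...`.  Members are compound keys; duplicates within a line are
#' collapsed.
#'
#' @param path Path to a GMT file.
#' @return A data.frame with columns `pathway_id`, `pathway_name` and a
#'   list-column `members` (character vectors of unique compound keys).
#' @export
read_pathway_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(toks)
  if (any(nf < 3)) {
    stop("GMT line ", which(nf < 3)[1], " has fewer than 3 fields")
  }
  ids <- vapply(toks, `[[`, "", 1)
  .dup_msg(ids, "pathway_id")
  members <- lapply(toks, function(t) unique(t[-c(1, 2)]))
  if (any(lengths(members) == 0)) {
    stop("pathway with empty member set: ", ids[which(lengths(members) == 0)[1]])
  }
  df <- data.frame(pathway_id = ids,
                   pathway_name = vapply(toks, `[[`, "", 2),
                   stringsAsFactors = FALSE)
  df$members <- members
  df
}

#' Write a pathway map in GMT format
#' @param pathways Pathway data.frame as returned by [read_pathway_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathway_gmt <- function(pathways, path) {
  stopifnot(all(c("pathway_id", "pathway_name", "members") %in%
                colnames(pathways)))
  lines <- vapply(seq_len(nrow(pathways)), function(i) {
    paste(c(pathways$pathway_id[i], pathways$pathway_name[i],
            pathways$members[[i]]), collapse = "\t")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Check that an abundance matrix and metadata describe the same samples
#' @param mat Abundance matrix.
#' @param metadata Metadata data.frame.
#' @return `TRUE`, invisibly; otherwise an error naming the mismatch.
#' @export
check_samples_match <- function(mat, metadata) {
  a <- rownames(mat)
  b <- metadata$sample_id
  only_a <- setdiff(a, b)
  only_b <- setdiff(b, a)
  if (length(only_a) || length(only_b)) {
    stop("sample sets differ; only in matrix: ",
         paste(utils::head(only_a, 3), collapse = ", "),
         "; only in metadata: ",
         paste(utils::head(only_b, 3), collapse = ", "))
  }
  invisible(TRUE)
}
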