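## Study-level data model: one row per toxicology study, substance-level
## aggregation of LD50 / NOAEL endpoints, and the plain-text interchange
## formats (study table, fingerprints, descriptor table).

#' Recognised endpoint and guideline codes
#'
#' `oral_endpoints()` returns the endpoint codes used throughout the package;
#' `oral_guidelines()` the OECD test-guideline codes. The mapping between the
#' two is fixed: TG 401/420/423/425 are acute oral designs, TG 407 is the
#' 28-day and TG 408 the 90-day repeated-dose design; `"other"` is allowed
#' with any endpoint.
#'
#' @return Character vector of codes.
#' @export
oral_endpoints <- function() c("acute_oral", "repeated_28d", "repeated_90d")

#' @rdname oral_endpoints
#' @export
oral_guidelines <- function()
  c("TG401", "TG420", "TG423", "TG425", "TG407", "TG408", "other")

study_qualifiers <- function() c("exact", "greater_than", "greater_equal")

guideline_endpoint_map <- function() {
  c(TG401 = "acute_oral", TG420 = "acute_oral", TG423 = "acute_oral",
    TG425 = "acute_oral", TG407 = "repeated_28d", TG408 = "repeated_90d")
}

study_columns <- function()
  c("substance_id", "endpoint", "guideline", "klimisch", "key_study",
    "read_across", "value", "qualifier")

#' Validate a study table
#'
#' Checks a data frame of study records against the dossier schema: column
#' presence, enum membership, positive endpoint values (mg/kg b.w.), Klimisch
#' scores in 1--4, and the fixed endpoint/guideline pairing. Failures are
#' reported with the offending row indices so malformed exports can be traced
#' back to their source lines.
#'
#' @param df Data frame with columns `substance_id`, `endpoint`, `guideline`,
#'   `klimisch`, `key_study`, `read_across`, `value`, `qualifier`.
#' @return The validated data frame (character/logical/numeric column types
#'   coerced), with class `"study_table"` prepended.
#' @export
as_study_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(study_columns(), names(df))
  if (length(missing))
    stop("study table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[study_columns()]
  df$substance_id <- as.character(df$substance_id)
  df$endpoint  <- as.character(df$endpoint)
  df$guideline <- as.character(df$guideline)
  df$qualifier <- as.character(df$qualifier)
  df$klimisch  <- suppressWarnings(as.integer(df$klimisch))
  df$value     <- suppressWarnings(as.numeric(df$value))
  for (col in c("key_study", "read_across"))
    if (!is.logical(df[[col]]))
      df[[col]] <- as.logical(toupper(trimws(as.character(df[[col]]))) %in%
                              c("TRUE", "T", "1", "YES"))

  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop(sprintf("study table row(s) %s: %s",
                   paste(head(i, 10L), collapse = ", "), what), call. = FALSE)
  }
  bad_row(is.na(df$substance_id) | df$substance_id == "", "empty substance_id")
  bad_row(!df$endpoint %in% oral_endpoints(), "unknown endpoint code")
  bad_row(!df$guideline %in% oral_guidelines(), "unknown guideline code")
  bad_row(!df$qualifier %in% study_qualifiers(), "unknown value qualifier")
  bad_row(is.na(df$klimisch) | df$klimisch < 1L | df$klimisch > 4L,
          "Klimisch score must be an integer in 1..4")
  bad_row(is.na(df$value) | df$value <= 0,
          "endpoint value must be a positive number (mg/kg b.w.)")
  gmap <- guideline_endpoint_map()
  mapped <- df$guideline %in% names(gmap)
  bad_row(mapped & df$endpoint != unname(gmap[df$guideline]),
          "guideline is not valid for this endpoint")
  class(df) <- c("study_table", class(df))
  df
}

#' Read and write study tables
#'
#' The study table interchange format is a UTF-8 CSV or TSV with a header row
#' naming the eight schema columns (see [as_study_table()]). Censored limit
#' values ("> 2000", ">= 5000") are carried as `value` plus a `qualifier` of
#' `greater_than` / `greater_equal`; the round trip is lossless.
#'
#' @param path File path. The delimiter defaults to tab for `.tsv` files and
#'   comma otherwise; override with `sep`.
#' @param sep Field separator, `","` or `"\t"`.
#' @return `read_study_table()` a validated `study_table` data frame in file
#'   order; `write_study_table()` the path, invisibly.
#' @export
read_study_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   quote = "\"", comment.char = "", fileEncoding = "UTF-8")
  as_study_table(df)
}

#' @rdname read_study_table
#' @param df A study table (validated on the way out).
#' @export
write_study_table <- function(df, path, sep = NULL) {
  df <- as_study_table(df)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  write.table(as.data.frame(df), path, sep = sep, row.names = FALSE,
              quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Aggregate studies of one substance into a single endpoint value
#'
#' The substance-level endpoint is the arithmetic mean of the values of the
#' studies that pass the selection filter (Klimisch score, key-study flag,
#' guideline, ...). Censored values participate at their bound. A geometric
#' mean is available as an option; the default replicates the conventional
#' "average substance LD50".
#'
#' @param studies Study records for a single substance and endpoint.
#' @param filter `NULL` (keep all) or a predicate `function(df)` returning a
#'   logical vector over rows.
#' @param mean_type `"arithmetic"` (default) or `"geometric"`.
#' @return A one-row data frame (`substance_id`, `endpoint`, `mean_value`,
#'   `n_studies`, `selection`), or `NULL` when no study passes the filter.
#' @export
aggregate_substance_value <- function(studies, filter = NULL,
                                      mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  studies <- as_study_table(studies)
  if (length(unique(studies$substance_id)) != 1L)
    stop("aggregate_substance_value() expects studies of a single substance",
         call. = FALSE)
  if (length(unique(studies$endpoint)) != 1L)
    stop("aggregate_substance_value() expects studies of a single endpoint",
         call. = FALSE)
  keep <- if (is.null(filter)) rep(TRUE, nrow(studies)) else filter(studies)
  sel <- studies[keep, , drop = FALSE]
  if (nrow(sel) == 0L) return(NULL)
  m <- if (mean_type == "arithmetic") mean(sel$value) else
    exp(mean(log(sel$value)))
  data.frame(substance_id = sel$substance_id[1L], endpoint = sel$endpoint[1L],
             mean_value = m, n_studies = nrow(sel),
             selection = if (is.null(filter)) "all" else "filtered",
             stringsAsFactors = FALSE)
}

#' Aggregate a full study table to substance-level endpoints
#'
#' Applies [aggregate_substance_value()] per substance and endpoint and
#' stacks the results. Substances for which no study passes the filter are
#' dropped.
#'
#' @inheritParams aggregate_substance_value
#' @param endpoint Optional endpoint code to restrict to before aggregation.
#' @return Data frame with one row per (substance, endpoint) pair.
#' @export
aggregate_endpoints <- function(studies, filter = NULL,
                                mean_type = c("arithmetic", "geometric"),
                                endpoint = NULL) {
  mean_type <- match.arg(mean_type)
  studies <- as_study_table(studies)
  if (!is.null(endpoint)) studies <- studies[studies$endpoint %in% endpoint, ]
  if (nrow(studies) == 0L)
    return(data.frame(substance_id = character(), endpoint = character(),
                      mean_value = numeric(), n_studies = integer(),
                      selection = character(), stringsAsFactors = FALSE))
  parts <- split(seq_len(nrow(studies)),
                 list(studies$substance_id, studies$endpoint), drop = TRUE)
  out <- lapply(parts, function(i)
    aggregate_substance_value(studies[i, , drop = FALSE], filter, mean_type))
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(data.frame(substance_id = character(),
                                      endpoint = character(),
                                      mean_value = numeric(),
                                      n_studies = integer(),
                                      selection = character()))
  rownames(out) <- NULL
  out[order(out$substance_id, out$endpoint), , drop = FALSE]
}

#' Binary oral-toxicant label from an aggregated acute endpoint
#'
#' A substance is an oral toxicant when its aggregated acute-oral LD50 is
#' strictly below the threshold (default 2,000 mg/kg b.w.). A mean of exactly
#' 2,000 is a non-toxicant: limit-dose results reported at the threshold fall
#' in the "not classified" class.
#'
#' @param agg Aggregated endpoint row(s) as returned by
#'   [aggregate_endpoints()], or a numeric vector of mean LD50 values.
#' @param threshold Classification threshold in mg/kg b.w.
#' @return Logical vector, `TRUE` for toxicants.
#' @export
label_toxicant <- function(agg, threshold = 2000) {
  if (is.data.frame(agg)) {
    if (!all(agg$endpoint == "acute_oral"))
      stop("label_toxicant() applies to acute_oral aggregates", call. = FALSE)
    v <- agg$mean_value
  } else v <- as.numeric(agg)
  v < threshold
}

#' Klimisch-1 key-study selection filter
#'
#' Convenience predicate for the modelling dataset convention: experimental
#' key studies with the stated maximum Klimisch score.
#'
#' @param max_klimisch Highest acceptable Klimisch score.
#' @param key_only Keep only registrant-designated key studies.
#' @param exclude_read_across Drop read-across records.
#' @return A predicate function usable as the `filter` argument of the
#'   aggregation functions.
#' @export
study_filter <- function(max_klimisch = 1L, key_only = TRUE,
                         exclude_read_across = TRUE) {
  force(max_klimisch); force(key_only); force(exclude_read_across)
  function(df) {
    keep <- df$klimisch <= max_klimisch
    if (key_only) keep <- keep & df$key_study
    if (exclude_read_across) keep <- keep & !df$read_across
    keep
  }
}

## ---- fingerprints ----------------------------------------------------------

#' Read and write binary fingerprints
#'
#' Fingerprints are stored one substance per line as `substance_id` TAB
#' hex-encoded bit set, preceded by a header line `#length <n>` declaring the
#' common bit length. In memory they are a logical matrix with substances in
#' rows (rownames = substance ids) and bit positions in columns.
#'
#' @param path File path.
#' @return `read_fingerprints()` a logical matrix; `write_fingerprints()` the
#'   path, invisibly.
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !grepl("^#length\\s+\\d+$", lines[1L]))
    stop("fingerprint file must start with a '#length <n>' header",
         call. = FALSE)
  n_bits <- as.integer(sub("^#length\\s+", "", lines[1L]))
  body <- lines[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  hex <- vapply(parts, `[[`, character(1), 2L)
  if (anyDuplicated(ids))
    stop("duplicate substance ids in fingerprint file", call. = FALSE)
  mat <- t(vapply(hex, hex_to_bits, logical(n_bits), n_bits = n_bits))
  rownames(mat) <- ids
  mat
}

#' @rdname read_fingerprints
#' @param fp Logical (or 0/1) matrix of fingerprints, substances in rows.
#' @export
write_fingerprints <- function(fp, path) {
  fp <- as.matrix(fp) != 0
  if (is.null(rownames(fp)))
    stop("fingerprint matrix needs substance ids as rownames", call. = FALSE)
  lines <- c(sprintf("#length %d", ncol(fp)),
             paste0(rownames(fp), "\t",
                    apply(fp, 1L, bits_to_hex)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

hex_to_bits <- function(h, n_bits) {
  nyb <- strtoi(strsplit(h, "")[[1L]], base = 16L)
  if (anyNA(nyb)) stop("invalid hex fingerprint: ", h, call. = FALSE)
  bits <- as.logical(unlist(lapply(nyb, function(v)
    bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0L)))
  if (length(bits) < n_bits) bits <- c(bits, rep(FALSE, n_bits - length(bits)))
  bits[seq_len(n_bits)]
}

bits_to_hex <- function(bits) {
  n <- length(bits)
  pad <- (4L - n %% 4L) %% 4L
  bits <- c(as.logical(bits), rep(FALSE, pad))
  nyb <- vapply(seq_len(length(bits) / 4L), function(i) {
    b <- bits[(4L * i - 3L):(4L * i)]
    sum(b * c(8L, 4L, 2L, 1L))
  }, numeric(1))
  paste(sprintf("%x", nyb), collapse = "")
}

## ---- descriptors and hazard flags ------------------------------------------

#' Read and write a molecular descriptor table
#'
#' CSV with a `substance_id` column plus one named numeric column per
#' descriptor. Modelled substances must have complete descriptor vectors;
#' rows with missing values are rejected unless `allow_missing = TRUE`.
#'
#' @param path File path.
#' @param allow_missing Keep rows with `NA` descriptor values.
#' @return `read_descriptors()` a data frame with `substance_id` first.
#' @export
read_descriptors <- function(path, allow_missing = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                   check.names = FALSE, fileEncoding = "UTF-8")
  if (!"substance_id" %in% names(df))
    stop("descriptor table is missing required column: substance_id",
         call. = FALSE)
  df$substance_id <- as.character(df$substance_id)
  num_cols <- setdiff(names(df), "substance_id")
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  if (!allow_missing) {
    ok <- complete.cases(df[num_cols])
    if (!all(ok))
      stop("descriptor rows with missing values: ",
           paste(head(which(!ok), 10L), collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_descriptors
#' @param df Descriptor data frame.
#' @export
write_descriptors <- function(df, path) {
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

hazard_codes <- function() c("H300", "H301", "H302", "H303", "H304", "H305")

hazard_statuses <- function()
  c("positive", "negative", "data_lacking", "inconclusive")

#' Validate a hazard-flag table
#'
#' Wide table: `substance_id` plus one column per GHS oral/aspiration hazard
#' code (H300--H305), values in `positive` / `negative` / `data_lacking` /
#' `inconclusive`. "Negative" is the "conclusive but not sufficient for
#' classification" category.
#'
#' @param df Data frame to validate.
#' @return The validated data frame.
#' @export
as_hazard_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"substance_id" %in% names(df))
    stop("hazard table is missing required column: substance_id", call. = FALSE)
  present <- intersect(hazard_codes(), names(df))
  if (!length(present))
    stop("hazard table has no H300..H305 columns", call. = FALSE)
  for (h in present) {
    df[[h]] <- as.character(df[[h]])
    bad <- which(!df[[h]] %in% hazard_statuses())
    if (length(bad))
      stop(sprintf("hazard table row(s) %s: invalid %s status",
                   paste(head(bad, 10L), collapse = ", "), h), call. = FALSE)
  }
  df
}
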