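# Readers and writers for the tabular artifacts the pipeline exchanges:
# weighted edge tables (STRING/STITCH-style exports), gene-set collections
# (GMT), node-attribute tables, alias maps, expression matrices, survival
# tables and morphometry tables.  All plain TSV, UTF-8.

# Unicode hyphen variants seen in database exports are normalized to ASCII.
normalize_ids <- function(x) {
  gsub("[\u2010\u2011\u2012\u2013\u2014\u2212]", "-", as.character(x))
}

#' Construct a chemical/protein interaction table
#'
#' An interaction table is the tabular (pre-graph) form of a weighted
#' undirected interaction network: one row per edge with a confidence score
#' in \[0, 1\] and a node kind (`"protein"` or `"chemical"`) per endpoint.
#' Self-pairs are dropped and duplicate undirected pairs are collapsed,
#' keeping the maximum confidence.
#'
#' @param node_a,node_b Character vectors of endpoint identifiers.
#' @param confidence Numeric vector of edge confidences in \[0, 1\].
#' @param kind_a,kind_b Endpoint kinds, `"protein"` or `"chemical"`.
#' @return A `data.frame` of class `interaction_table` with columns
#'   `node_a`, `node_b`, `confidence`, `kind_a`, `kind_b`.
#' @export
interaction_table <- function(node_a, node_b, confidence,
                              kind_a = "protein", kind_b = "protein") {
  df <- data.frame(
    node_a = normalize_ids(node_a),
    node_b = normalize_ids(node_b),
    confidence = as.numeric(confidence),
    kind_a = rep_len(as.character(kind_a), length(node_a)),
    kind_b = rep_len(as.character(kind_b), length(node_a)),
    stringsAsFactors = FALSE
  )
  if (any(df$confidence < 0 | df$confidence > 1, na.rm = TRUE))
    stop_hb("hb_bad_confidence", "confidence scores must lie in [0, 1]")
  clean_interactions(df)
}

# Drop self-pairs, collapse duplicate undirected pairs (max confidence wins).
clean_interactions <- function(df) {
  self <- df$node_a == df$node_b
  if (any(self)) {
    message(sum(self), " self-pair(s) dropped")
    df <- df[!self, , drop = FALSE]
  }
  # canonical orientation: lexicographically smaller id first
  flip <- df$node_a > df$node_b
  if (any(flip)) {
    tmp <- df$node_a[flip]; df$node_a[flip] <- df$node_b[flip]; df$node_b[flip] <- tmp
    tmp <- df$kind_a[flip]; df$kind_a[flip] <- df$kind_b[flip]; df$kind_b[flip] <- tmp
  }
  key <- paste(df$node_a, df$node_b, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(key, -df$confidence)
    df <- df[ord, , drop = FALSE]
    dup <- duplicated(key[ord])
    message(sum(dup), " duplicate undirected pair(s) collapsed (max confidence kept)")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("interaction_table", "data.frame")
  df
}

#' Read a weighted edge table
#'
#' Parses a TSV edge table with columns `node_a`, `node_b`, `score` (header
#' required; extra columns `kind_a`/`kind_b` are honoured).  Two score
#' dialects are supported: the 0-999 integer combined-score dialect used by
#' STRING/STITCH exports (divided by 1000 on read) and the unit-interval
#' dialect.  `"auto"` picks the integer dialect when any score exceeds 1.
#' Duplicate undirected pairs are collapsed keeping the maximum confidence;
#' self-pairs are dropped (both with a logged count).
#'
#' @param path Path to a TSV file.
#' @param dialect `"auto"`, `"string9"` (0-999) or `"unit"` (\[0, 1\]).
#' @return An [interaction_table()].
#' @export
read_edge_table <- function(path, dialect = c("auto", "string9", "unit")) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(df) == 0L)
    stop_hb("hb_empty_file", "edge table '%s' has no rows", path)
  if (ncol(df) < 3L)
    stop_hb("hb_bad_format", "edge table '%s' needs >= 3 columns", path)
  score <- as.numeric(df[[3L]])
  if (anyNA(score) || any(score < 0) || any(score > 999))
    stop_hb("hb_bad_score", "unknown score dialect in '%s'", path)
  if (dialect == "auto") dialect <- if (any(score > 1)) "string9" else "unit"
  conf <- if (dialect == "string9") score / 1000 else score
  interaction_table(
    node_a = df[[1L]], node_b = df[[2L]], confidence = conf,
    kind_a = if ("kind_a" %in% names(df)) df$kind_a else "protein",
    kind_b = if ("kind_b" %in% names(df)) df$kind_b else "protein"
  )
}

#' Write an interaction table as TSV (unit-interval score dialect)
#'
#' @param tab An [interaction_table()].
#' @param path Output path.
#' @export
write_edge_table <- function(tab, path) {
  df <- as.data.frame(tab)
  names(df)[3] <- "score"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name <TAB> description <TAB> gene...`.
#' Genes are de-duplicated within each set.  Duplicate set names are an
#' error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3L
  if (any(bad))
    stop_hb("hb_bad_format", "GMT line(s) without name, description and >= 1 gene")
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop_hb("hb_duplicate_set", "duplicate gene-set name(s): %s",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(normalize_ids(f[-(1:2)])))
  names(sets) <- normalize_ids(nm)
  attr(sets, "description") <- stats::setNames(vapply(fields, `[[`, "", 2L), names(sets))
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character vectors (optionally with a
#'   `description` attribute as produced by [read_gmt()]).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Read a node-attribute table (TSV: node, key, value)
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `node`, `key`, `value`.
#' @export
read_node_attributes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                          colClasses = "character")
  names(df)[1:3] <- c("node", "key", "value")
  df$node <- normalize_ids(df$node)
  df
}

#' Write a node-attribute table
#'
#' @param df Data.frame with columns `node`, `key`, `value`.
#' @param path Output path.
#' @export
write_node_attributes <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an alias map (TSV: synonym, canonical)
#'
#' @param path Path to a TSV file.
#' @return Named character vector mapping synonym to canonical identifier.
#' @export
read_alias_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                          colClasses = "character")
  stats::setNames(normalize_ids(df[[2L]]), normalize_ids(df[[1L]]))
}

#' Resolve identifiers through an alias map
#'
#' Names present in the map are replaced by their canonical form; names
#' absent from the map pass through unchanged and are listed in the
#' `unmapped` report.  Canonical identifiers are fixed points.
#'
#' @param names Character vector of identifiers.
#' @param aliases Named character vector (synonym -> canonical).
#' @return List with elements `resolved` (character vector, same length and
#'   order as `names`) and `unmapped` (names not found in the map).
#' @export
resolve_aliases <- function(names, aliases) {
  names <- normalize_ids(names)
  hit <- names %in% names(aliases)
  resolved <- names
  resolved[hit] <- unname(aliases[names[hit]])
  list(resolved = resolved, unmapped = unique(names[!hit & !(names %in% aliases)]))
}

#' Read an expression matrix (TSV, first column gene id, header of sample ids)
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                          check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- normalize_ids(df[[1L]])
  m
}

#' Write an expression matrix as TSV
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a patient survival table
#'
#' TSV with columns `patient_id`, `time_months`, `event`, then one numeric
#' column per gene.
#'
#' @param path Path to a TSV file.
#' @return A data.frame of class `survival_table`.
#' @export
read_survival_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                          check.names = FALSE)
  as_survival_table(df)
}

as_survival_table <- function(df) {
  needed <- c("patient_id", "time_months", "event")
  if (!all(needed %in% names(df)))
    stop_hb("hb_bad_format", "survival table needs columns %s",
            paste(needed, collapse = ", "))
  if (any(df$time_months <= 0))
    stop_hb("hb_bad_format", "survival times must be positive")
  if (!all(df$event %in% c(0, 1)))
    stop_hb("hb_bad_format", "event flags must be 0 or 1")
  class(df) <- c("survival_table", "data.frame")
  df
}

#' Write a patient survival table as TSV
#'
#' @param df A `survival_table` data.frame.
#' @param path Output path.
#' @export
write_survival_table <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a nuclear morphometry table
#'
#' TSV with columns `area`, `aspect`, `areabox`, `radius_ratio`, `roundness`
#' (additional columns such as `class` pass through).
#'
#' @param path Path to a TSV file.
#' @return A data.frame of nucleus records.
#' @export
read_morphometry <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  needed <- c("area", "aspect", "areabox", "radius_ratio", "roundness")
  if (!all(needed %in% names(df)))
    stop_hb("hb_bad_format", "morphometry table needs columns %s",
            paste(needed, collapse = ", "))
  df
}

#' Write a nuclear morphometry table as TSV
#'
#' @param df Data.frame of nucleus records.
#' @param path Output path.
#' @export
write_morphometry <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
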