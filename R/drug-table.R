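#' Per-drug feature table
#'
#' A `drug_feature_table` holds the binary (or, for side effects, dose-coded)
#' annotation profile of a set of drugs for one feature category.  Entries are
#' 0/1 for targets, pathways, enzymes and transporters; side-effect entries
#' are 0 (absent), 1 (reported at low dose) or 2 (reported at high dose).
#'
#' @param matrix integer matrix, drugs in rows, features in columns.  Row
#'   names (or `drug_ids`) identify drugs; column names identify features.
#' @param category feature category, one of `"target"`, `"pathway"`,
#'   `"enzyme"`, `"transporter"`, `"side_effect"`.
#' @param drug_ids optional character vector of drug identifiers overriding
#'   the row names.
#' @return an object of class `drug_feature_table` with elements `drug_ids`,
#'   `category` and `matrix`.
#' @examples
#' m <- matrix(rbinom(20, 1, 0.3), 4, 5,
#'             dimnames = list(paste0("D", 1:4), paste0("f", 1:5)))
#' drug_feature_table(m, "target")
#' @export
drug_feature_table <- function(matrix, category, drug_ids = NULL) {
  category <- match.arg(category, c("target", "pathway", "enzyme",
                                    "transporter", "side_effect"))
  m <- as.matrix(matrix)
  storage.mode(m) <- "integer"
  if (is.null(drug_ids)) drug_ids <- rownames(m)
  stop_if_not(!is.null(drug_ids), "drug identifiers are required")
  drug_ids <- as.character(drug_ids)
  stop_if_not(length(drug_ids) == nrow(m),
              "length(drug_ids) must equal nrow(matrix)")
  stop_if_not(!anyDuplicated(drug_ids), "drug_ids must be unique")
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  rownames(m) <- drug_ids
  vmax <- drug_value_max(category)
  bad <- m < 0L | m > vmax
  if (any(bad, na.rm = TRUE) || anyNA(m)) {
    stop(sprintf("entries must be integers in 0..%d for category '%s'",
                 vmax, category), call. = FALSE)
  }
  structure(list(drug_ids = drug_ids, category = category, matrix = m),
            class = "drug_feature_table")
}

drug_value_max <- function(category) {
  if (identical(category, "side_effect")) 2L else 1L
}

#' @export
print.drug_feature_table <- function(x, ...) {
  cat(sprintf("Drug feature table: %d drugs x %d '%s' features (density %.3f)\n",
              nrow(x$matrix), ncol(x$matrix), x$category,
              mean(x$matrix != 0)))
  invisible(x)
}

#' @export
dim.drug_feature_table <- function(x) dim(x$matrix)

#' Read / write a drug feature table
#'
#' Tab-separated text: first column the drug identifier, remaining columns
#' integer feature values, header row of feature identifiers.
#'
#' @param path file path.
#' @param category feature category (see [drug_feature_table()]).
#' @return `read_drug_table()` returns a [drug_feature_table()];
#'   `write_drug_table()` invisibly returns `path`.
#' @export
read_drug_table <- function(path, category) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  drug_feature_table(m, category, drug_ids = ids)
}

#' @param table a [drug_feature_table()].
#' @rdname read_drug_table
#' @export
write_drug_table <- function(table, path) {
  df <- data.frame(drug_id = table$drug_ids, table$matrix,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
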