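# Delimited SMILES+logS table I/O and dataset cleaning.

#' Load a SMILES table
#'
#' Reads a delimited table with a header. Column names are configurable; by
#' default a `smiles` column and a numeric `logS` label column are expected.
#' No chemistry is parsed at this stage.
#'
#' @param path File path.
#' @param smiles_col,label_col Column names.
#' @param sep Field separator (comma by default).
#' @return A data frame with columns `smiles` (character) and `logS` (numeric),
#'   plus `id` if the file has one; rows in file order.
#' @export
read_smiles_table <- function(path, smiles_col = "smiles", label_col = "logS",
                              sep = ",") {
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  missing <- setdiff(c(smiles_col, label_col), names(df))
  if (length(missing) > 0)
    stop(sprintf("column%s %s not found in '%s' (available: %s)",
                 if (length(missing) > 1) "s" else "",
                 paste(sprintf("'%s'", missing), collapse = ", "), path,
                 paste(sprintf("'%s'", names(df)), collapse = ", ")),
         call. = FALSE)
  out <- data.frame(smiles = as.character(df[[smiles_col]]),
                    logS = suppressWarnings(as.numeric(df[[label_col]])),
                    stringsAsFactors = FALSE)
  if ("id" %in% names(df) && !"id" %in% c(smiles_col, label_col))
    out$id <- as.character(df$id)
  out
}

#' Write a SMILES table
#'
#' @param records Data frame with `smiles` and `logS` columns.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_smiles_table <- function(records, path, sep = ",") {
  stopifnot(all(c("smiles", "logS") %in% names(records)))
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Clean a SMILES dataset
#'
#' Removes records with missing or empty SMILES or non-finite labels, drops
#' SMILES that fail to parse (with a warning naming them), and removes
#' duplicate molecules. Duplicates are detected by canonical-structure
#' equality -- two different SMILES writings of the same molecule count as one
#' record -- keeping the first occurrence. Row order is otherwise preserved,
#' and cleaning is idempotent.
#'
#' @param records Data frame with `smiles` and `logS` columns (as returned by
#'   [read_smiles_table()]).
#' @return The cleaned data frame.
#' @examples
#' \donttest{
#' df <- data.frame(smiles = c("CCO", "OCC"), logS = c(-0.2, -0.3))
#' clean_records(df)  # one row: CCO, -0.2
#' }
#' @export
clean_records <- function(records) {
  stopifnot(all(c("smiles", "logS") %in% names(records)))
  if (nrow(records) == 0) return(records)
  keep <- !is.na(records$smiles) & nzchar(trimws(records$smiles)) &
    is.finite(records$logS)
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0) {
    rownames(records) <- NULL
    return(records)
  }
  can <- canonical_smiles(records$smiles)
  if (anyNA(can)) {
    warning(sprintf("dropping %d unparseable SMILES: %s", sum(is.na(can)),
                    paste(utils::head(records$smiles[is.na(can)], 5),
                          collapse = ", ")), call. = FALSE)
    records <- records[!is.na(can), , drop = FALSE]
    can <- can[!is.na(can)]
  }
  records <- records[!duplicated(can), , drop = FALSE]
  rownames(records) <- NULL
  records
}
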