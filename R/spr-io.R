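# CSV round-trip for self-paced-reading datasets.

SPR_COLUMNS <- c(participant = "integer", item = "integer",
                 condition = "character", is_filler = "logical",
                 list_position = "integer", word_index = "integer",
                 word = "character", word_length = "integer",
                 region = "character", rt = "numeric", correct = "integer")

#' Write a self-paced-reading dataset to CSV
#'
#' Fixed, documented header (`participant, item, condition, is_filler,
#' list_position, word_index, word, word_length, region, rt, correct`);
#' the round trip through [read_spr()] is lossless.
#'
#' @param data Dataset from [generate_exp1()]/[generate_exp2()] (or any
#'   data frame with the same columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spr <- function(data, path) {
  missing_cols <- setdiff(names(SPR_COLUMNS), names(data))
  if (length(missing_cols) > 0) {
    stop("dataset is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(data[names(SPR_COLUMNS)], path, row.names = FALSE)
  invisible(path)
}

#' Read a self-paced-reading dataset from CSV
#'
#' Validates the header and field types; malformed rows raise an error
#' naming the offending line number(s) of the file.
#'
#' @param path CSV file written by [write_spr()].
#' @return The dataset as a data frame.
#' @export
read_spr <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(SPR_COLUMNS), names(d))
  if (length(missing_cols) > 0) {
    stop("malformed dataset ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  d <- d[names(SPR_COLUMNS)]
  numeric_cols <- c("participant", "item", "list_position", "word_index",
                    "word_length", "rt", "correct")
  for (cn in numeric_cols) {
    v <- suppressWarnings(as.numeric(d[[cn]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop("malformed value in column '", cn, "' of ", path, " at line(s) ",
           paste(utils::head(bad + 1L, 5), collapse = ", "),
           " (header is line 1)")
    }
  }
  bad_rt <- which(d$rt <= 0)
  if (length(bad_rt) > 0) {
    stop("non-positive rt in ", path, " at line(s) ",
         paste(utils::head(bad_rt + 1L, 5), collapse = ", "))
  }
  d$is_filler <- as.logical(d$is_filler)
  d
}
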