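# 5-point Likert values are stored as integers on the centered scale
# {-2, -1, 0, +1, +2}. Two sentinels exist: NA_integer_ for a missing answer
# and `likert_dk` for an explicit "Don't know", which is only admissible on
# items that offer that option (the behavior items by default). The two are
# distinct because "Don't know" responders are excluded only from analyses of
# the affected item, not from the study.

#' Sentinel for an explicit "Don't know" response
#'
#' Stored value used to distinguish a deliberate "Don't know" answer from a
#' missing one (`NA`). It lies outside the valid Likert range so that any
#' arithmetic use without prior handling is loudly wrong.
#'
#' @format An integer scalar.
#' @seealso [is_dont_know()], [recode_likert()]
#' @export
likert_dk <- -9L

#' Test for the "Don't know" sentinel
#'
#' @param x An integer vector of stored Likert values.
#' @return A logical vector, `TRUE` where `x` is the "Don't know" sentinel.
#'   `NA` values return `FALSE` (missing is not "Don't know").
#' @export
is_dont_know <- function(x) {
  !is.na(x) & x == likert_dk
}

#' Recode raw Likert responses to the centered scale
#'
#' Converts raw survey answers to the internal centered coding. Two source
#' codings are supported: `"raw"` for 1..5 answers (recoded as `x - 3`, so the
#' midpoint 3 maps to 0 and the endpoints to -2/+2) and `"centered"` for data
#' already on -2..+2 (validated, passed through). The declared "Don't know"
#' code maps to [likert_dk] and the missing code to `NA`.
#'
#' @param x A character or numeric vector of raw responses.
#' @param coding `"centered"` (default) or `"raw"`.
#' @param dk_code String marking a "Don't know" response in the source
#'   (default `"DK"`).
#' @param na_codes Strings treated as missing (default empty string and `"NA"`).
#' @param item Optional item name used in error messages.
#' @return An integer vector on the centered scale with sentinels.
#' @examples
#' recode_likert(c("1", "3", "5"), coding = "raw")   # -2, 0, 2
#' recode_likert(c("-2", "DK", ""))                  # -2, likert_dk, NA
#' @export
recode_likert <- function(x, coding = c("centered", "raw"), dk_code = "DK",
                          na_codes = c("", "NA"), item = NULL) {
  coding <- arg_match(coding)
  x_chr <- trimws(as.character(x))
  out <- rep(NA_integer_, length(x_chr))
  is_na <- is.na(x_chr) | x_chr %in% na_codes
  is_dk <- !is_na & x_chr == dk_code
  out[is_dk] <- likert_dk

  plain <- !is_na & !is_dk
  val <- suppressWarnings(as.numeric(x_chr[plain]))
  bad_num <- is.na(val) | val != round(val)
  rng <- if (coding == "raw") c(1, 5) else c(-2, 2)
  bad_rng <- !bad_num & (val < rng[1] | val > rng[2])
  if (any(bad_num) || any(bad_rng)) {
    rows <- which(plain)[bad_num | bad_rng]
    abort(glue::glue(
      "Invalid Likert response{if (length(rows) > 1) 's' else ''} ",
      "{if (!is.null(item)) paste0('for item `', item, '` ') else ''}",
      "at row{if (length(rows) > 1) 's' else ''} ",
      "{paste(head(rows, 5), collapse = ', ')}: expected an integer in ",
      "{rng[1]}..{rng[2]}, `{dk_code}` or missing."
    ))
  }
  out[plain] <- as.integer(val) - if (coding == "raw") 3L else 0L
  out
}
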