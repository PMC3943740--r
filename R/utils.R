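# shared helpers

#' Normalize gene/protein symbols
#'
#' Uppercases and strips surrounding whitespace. Symbol case varies across
#' interaction databases, so all ingest paths funnel through this.
#'
#' @param x character vector of symbols.
#' @return character vector, uppercased and trimmed.
#' @export
norm_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

# round-half-up at `digits` decimals; base round() is banker's rounding,
# which would turn 94.95 into 94.9 or 95.0 unpredictably for reporting
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Construct a labelled protein set
#'
#' @param symbols character vector of protein symbols (normalized on entry).
#' @param label free-text role, e.g. `"seed"`, `"known_target"`,
#'   `"putative_target"`.
#' @param allow_empty permit an empty set (used for degenerate selections);
#'   by default an empty set is an error because the pipeline stages require
#'   nonempty inputs.
#' @return an object of class `protein_set` with elements `label` and
#'   `symbols` (sorted, unique, uppercase).
#' @export
protein_set <- function(symbols, label = "set", allow_empty = FALSE) {
  s <- norm_symbols(symbols)
  s <- sort(unique(s[nzchar(s) & !is.na(s)]))
  if (!allow_empty && length(s) == 0L) {
    stop("protein set '", label, "' contains no symbols")
  }
  structure(list(label = label, symbols = s), class = "protein_set")
}

#' @export
print.protein_set <- function(x, ...) {
  cat("<protein_set '", x$label, "': ", length(x$symbols), " symbols>\n",
      sep = "")
  invisible(x)
}

# accept either a protein_set or a plain character vector of symbols
.sym <- function(x) {
  if (inherits(x, "protein_set")) x$symbols else {
    s <- norm_symbols(x)
    unique(s[nzchar(s) & !is.na(s)])
  }
}
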