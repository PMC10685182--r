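#' Parse STR allele labels
#'
#' STR alleles are named by their repeat count, with microvariants carrying a
#' partial-repeat suffix (`"9.3"` = 9 full repeats plus 3 bases). The sentinel
#' `"OL"` marks an off-ladder call. Labels are kept as strings throughout the
#' package and compared through their parsed `(repeat, step)` key, which
#' avoids floating-point equality traps for microvariant alleles.
#'
#' @param labels character vector of allele labels.
#' @return data.frame with columns `label`, `rep` (integer repeat count),
#'   `step` (microvariant step 0-3), `ol` (logical). `rep`/`step` are `NA`
#'   for the OL sentinel.
#' @examples
#' parse_alleles(c("9", "9.3", "OL"))
#' @export
parse_alleles <- function(labels) {
  labels <- as.character(labels)
  ol <- labels == "OL"
  ok <- ol | grepl("^[0-9]+(\\.[123])?$", labels)
  if (!all(ok)) {
    stop(
      "malformed allele label(s): ",
      paste(unique(labels[!ok]), collapse = ", "),
      call. = FALSE
    )
  }
  rep_n <- step <- rep(NA_integer_, length(labels))
  rep_n[!ol] <- as.integer(sub("\\..*$", "", labels[!ol]))
  step[!ol] <- 0L
  has_step <- !ol & grepl(".", labels, fixed = TRUE)
  step[has_step] <- as.integer(sub("^.*\\.", "", labels[has_step]))
  data.frame(
    label = labels, rep = rep_n, step = step, ol = ol,
    stringsAsFactors = FALSE
  )
}

#' Sort allele labels numerically
#'
#' Orders by repeat count, then microvariant step; the OL sentinel sorts
#' last. Labels that are not STR repeat labels (permitted in standalone
#' statistics functions) fall back to lexical order after the numeric ones.
#'
#' @param labels character vector of allele labels.
#' @return the labels in canonical order.
#' @export
sort_alleles <- function(labels) {
  labels <- unique(as.character(labels))
  str_like <- is_valid_allele(labels)
  if (all(str_like)) {
    p <- parse_alleles(labels)
    p <- p[order(p$ol, p$rep, p$step), , drop = FALSE]
    p$label
  } else {
    c(if (any(str_like)) sort_alleles(labels[str_like]),
      sort(labels[!str_like]))
  }
}

is_valid_allele <- function(labels) {
  labels == "OL" | grepl("^[0-9]+(\\.[123])?$", as.character(labels))
}
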