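#' Define an STR panel
#'
#' A panel names the loci to be analysed and assigns each a chromosome class.
#' Autosomal loci are diploid in every sample; X loci are diploid in females
#' and hemizygous (single allele) in males. Loci of other classes (Y,
#' amelogenin, indels) are outside the panel model and simply not listed.
#'
#' @param locus character vector of locus names (unique).
#' @param chromosome character vector, one of `"autosomal"` or `"X"`,
#'   recycled if length 1.
#' @return a data.frame of class `str_panel` with columns `locus`,
#'   `chromosome`.
#' @examples
#' str_panel(c("vWA", "DXS10135"), c("autosomal", "X"))
#' @export
str_panel <- function(locus, chromosome) {
  locus <- as.character(locus)
  chromosome <- rep_len(as.character(chromosome), length(locus))
  if (anyDuplicated(locus)) {
    stop("duplicate locus names in panel: ",
         paste(unique(locus[duplicated(locus)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(chromosome %in% c("autosomal", "X"))) {
    stop("chromosome class must be 'autosomal' or 'X'", call. = FALSE)
  }
  out <- data.frame(locus = locus, chromosome = chromosome,
                    stringsAsFactors = FALSE)
  class(out) <- c("str_panel", "data.frame")
  out
}

#' Read / write a panel configuration
#'
#' The panel file is a small YAML document:
#' ```yaml
#' loci:
#'   - name: vWA
#'     chromosome: autosomal
#'   - name: DXS10135
#'     chromosome: X
#' ```
#'
#' @param path file path.
#' @return `read_panel()` returns an `str_panel`; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$loci)) stop("panel file has no 'loci' entry", call. = FALSE)
  str_panel(
    locus = vapply(doc$loci, function(l) as.character(l$name), character(1)),
    chromosome = vapply(doc$loci, function(l) as.character(l$chromosome),
                        character(1))
  )
}

#' @rdname read_panel
#' @param panel an `str_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "str_panel"))
  doc <- list(loci = lapply(seq_len(nrow(panel)), function(i) {
    list(name = panel$locus[i], chromosome = panel$chromosome[i])
  }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

panel_class <- function(panel, locus) {
  i <- match(locus, panel$locus)
  if (anyNA(i)) {
    stop("locus not in panel: ", paste(locus[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  panel$chromosome[i]
}
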