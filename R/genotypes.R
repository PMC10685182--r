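#' Construct a genotype table
#'
#' The central data container: sample metadata, a long table of calls, and
#' the panel. Calls hold two allele labels for diploid genotypes (`a1`,
#' `a2`; unordered) and a single label with `a2 = NA` for hemizygous male X
#' calls. Missing calls are simply absent rows; they are excluded from all
#' denominators rather than imputed.
#'
#' @param samples data.frame with columns `sample_id`, `sex` (`"M"`/`"F"`),
#'   `population`.
#' @param calls data.frame with columns `sample_id`, `locus`, `a1`, `a2`
#'   (character allele labels; `a2` `NA` for male X calls).
#' @param panel an [str_panel()].
#' @return object of class `genotype_table`.
#' @export
genotype_table <- function(samples, calls, panel) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  need_s <- c("sample_id", "sex", "population")
  if (!all(need_s %in% names(samples))) {
    stop("samples needs columns: ", paste(need_s, collapse = ", "),
         call. = FALSE)
  }
  need_c <- c("sample_id", "locus", "a1", "a2")
  if (!all(need_c %in% names(calls))) {
    stop("calls needs columns: ", paste(need_c, collapse = ", "),
         call. = FALSE)
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$sex <- as.character(samples$sex)
  samples$population <- as.character(samples$population)
  for (col in c("sample_id", "locus", "a1", "a2")) {
    calls[[col]] <- as.character(calls[[col]])
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in samples", call. = FALSE)
  }
  if (!all(samples$sex %in% c("M", "F"))) {
    stop("sex must be 'M' or 'F'", call. = FALSE)
  }
  if (!all(calls$sample_id %in% samples$sample_id)) {
    stop("calls reference unknown sample_id", call. = FALSE)
  }
  if (!all(calls$locus %in% panel$locus)) {
    bad <- setdiff(unique(calls$locus), panel$locus)
    stop("calls reference loci not in panel: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(calls[c("sample_id", "locus")])) {
    stop("more than one call for the same (sample, locus)", call. = FALSE)
  }
  bad1 <- !is_valid_allele(calls$a1)
  bad2 <- !is.na(calls$a2) & !is_valid_allele(calls$a2)
  if (any(bad1 | bad2)) {
    i <- which(bad1 | bad2)[1]
    stop(sprintf("malformed allele label '%s' (sample %s, locus %s)",
                 if (bad1[i]) calls$a1[i] else calls$a2[i],
                 calls$sample_id[i], calls$locus[i]), call. = FALSE)
  }
  chrom <- panel_class(panel, calls$locus)
  sex <- samples$sex[match(calls$sample_id, samples$sample_id)]
  hemi <- chrom == "X" & sex == "M"
  two <- hemi & !is.na(calls$a2)
  if (any(two & calls$a1 != calls$a2)) {
    i <- which(two & calls$a1 != calls$a2)[1]
    stop(sprintf(
      "male sample %s has two distinct alleles at X locus %s",
      calls$sample_id[i], calls$locus[i]), call. = FALSE)
  }
  # a duplicated identical allele in a hemizygous call collapses to one copy
  calls$a2[two] <- NA_character_
  if (any(!hemi & is.na(calls$a2))) {
    i <- which(!hemi & is.na(calls$a2))[1]
    stop(sprintf("diploid call with a single allele (sample %s, locus %s)",
                 calls$sample_id[i], calls$locus[i]), call. = FALSE)
  }
  # genotypes are unordered: store diploid calls in canonical allele order
  dip <- !is.na(calls$a2)
  if (any(dip)) {
    canon <- sort_alleles(c(calls$a1, calls$a2[dip]))
    swap <- dip & match(calls$a2, canon) < match(calls$a1, canon)
    if (any(swap)) {
      tmp <- calls$a1[swap]
      calls$a1[swap] <- calls$a2[swap]
      calls$a2[swap] <- tmp
    }
  }
  structure(
    list(samples = samples, calls = calls, panel = panel),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf(
    "genotype_table: %d samples (%d M / %d F), %d loci (%d autosomal, %d X), %d calls\n",
    nrow(x$samples), sum(x$samples$sex == "M"), sum(x$samples$sex == "F"),
    nrow(x$panel), sum(x$panel$chromosome == "autosomal"),
    sum(x$panel$chromosome == "X"), nrow(x$calls)))
  pops <- table(x$samples$population)
  cat("populations:",
      paste(sprintf("%s (n=%d)", names(pops), as.integer(pops)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Subset a genotype table by population
#'
#' @param x a `genotype_table`.
#' @param population population label(s) to keep.
#' @return a `genotype_table` restricted to those samples.
#' @export
subset_population <- function(x, population) {
  stopifnot(inherits(x, "genotype_table"))
  keep <- x$samples$population %in% population
  if (!any(keep)) stop("no samples in population ", population, call. = FALSE)
  samples <- x$samples[keep, , drop = FALSE]
  calls <- x$calls[x$calls$sample_id %in% samples$sample_id, , drop = FALSE]
  rownames(samples) <- rownames(calls) <- NULL
  genotype_table(samples, calls, x$panel)
}

# Allele matrix for one locus: 2-column character matrix for diploid rows
# (a2 NA for hemizygous). Optionally restricted by sex.
locus_calls <- function(x, locus, sex = c("both", "M", "F")) {
  sex <- match.arg(sex)
  cl <- x$calls[x$calls$locus == locus, , drop = FALSE]
  if (sex != "both") {
    s <- x$samples$sample_id[x$samples$sex == sex]
    cl <- cl[cl$sample_id %in% s, , drop = FALSE]
  }
  cl
}

#' Read a genotype table
#'
#' Two plain-text dialects are supported.
#' \describe{
#'   \item{wide}{one row per sample with columns `sample_id`, `sex`,
#'     `population`, then `<locus>_1` and `<locus>_2` per locus. Hemizygous
#'     male X calls leave `<locus>_2` empty; fully empty pairs are missing
#'     calls.}
#'   \item{long}{columns `sample_id`, `sex`, `population`, `locus`,
#'     `allele`; one row per allele copy, so a diploid genotype occupies two
#'     rows and a male X call one.}
#' }
#' Files are tab-separated with a header. Off-ladder alleles are written as
#' the literal string `OL` and preserved as such.
#'
#' @param path file path.
#' @param panel an [str_panel()] or path to a panel YAML file.
#' @param dialect `"wide"` or `"long"`.
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path, panel, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(panel)) panel <- read_panel(panel)
  stopifnot(inherits(panel, "str_panel"))
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  if (dialect == "wide") {
    meta <- c("sample_id", "sex", "population")
    if (!all(meta %in% names(raw))) {
      stop("wide file needs columns: ", paste(meta, collapse = ", "),
           call. = FALSE)
    }
    loci <- intersect(panel$locus,
                      unique(sub("_[12]$", "",
                                 setdiff(names(raw), meta))))
    calls_list <- vector("list", length(loci))
    for (j in seq_along(loci)) {
      lc <- loci[j]
      c1 <- raw[[paste0(lc, "_1")]]
      c2 <- raw[[paste0(lc, "_2")]]
      if (is.null(c1)) {
        stop("wide file lacks column ", paste0(lc, "_1"), call. = FALSE)
      }
      if (is.null(c2)) c2 <- rep("", nrow(raw))
      typed <- !(c1 == "" & c2 == "")
      if (any(c1 == "" & c2 != "")) {
        stop("call with empty first allele at locus ", lc, call. = FALSE)
      }
      if (!any(typed)) next
      calls_list[[j]] <- data.frame(
        sample_id = raw$sample_id[typed], locus = lc,
        a1 = c1[typed],
        a2 = ifelse(c2[typed] == "", NA_character_, c2[typed]),
        stringsAsFactors = FALSE
      )
    }
    calls <- do.call(rbind, calls_list)
    samples <- raw[meta]
  } else {
    need <- c("sample_id", "sex", "population", "locus", "allele")
    if (!all(need %in% names(raw))) {
      stop("long file needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    samples <- unique(raw[c("sample_id", "sex", "population")])
    key <- interaction(raw$sample_id, raw$locus, drop = TRUE)
    parts <- split(raw, key)
    calls <- do.call(rbind, lapply(parts, function(p) {
      if (nrow(p) > 2) {
        stop(sprintf(">2 allele rows for sample %s locus %s",
                     p$sample_id[1], p$locus[1]), call. = FALSE)
      }
      data.frame(
        sample_id = p$sample_id[1], locus = p$locus[1],
        a1 = p$allele[1],
        a2 = if (nrow(p) == 2) p$allele[2] else NA_character_,
        stringsAsFactors = FALSE
      )
    }))
    calls <- calls[calls$locus %in% panel$locus, , drop = FALSE]
  }
  rownames(calls) <- NULL
  if (is.null(calls)) {
    calls <- data.frame(sample_id = character(), locus = character(),
                        a1 = character(), a2 = character(),
                        stringsAsFactors = FALSE)
  }
  genotype_table(samples, calls, panel)
}

#' Write a genotype table
#'
#' @param x a `genotype_table`.
#' @param path output file path (UTF-8, tab-separated, with header).
#' @param dialect `"wide"` or `"long"`; see [read_genotypes()].
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "genotype_table"))
  if (dialect == "wide") {
    out <- x$samples
    for (lc in x$panel$locus) {
      cl <- x$calls[x$calls$locus == lc, , drop = FALSE]
      i <- match(out$sample_id, cl$sample_id)
      out[[paste0(lc, "_1")]] <- ifelse(is.na(i), "", cl$a1[i])
      out[[paste0(lc, "_2")]] <- ifelse(is.na(i) | is.na(cl$a2[i]), "",
                                        cl$a2[i])
    }
  } else {
    cl <- x$calls
    sx <- x$samples[match(cl$sample_id, x$samples$sample_id), ]
    one <- data.frame(sample_id = cl$sample_id, sex = sx$sex,
                      population = sx$population, locus = cl$locus,
                      allele = cl$a1, stringsAsFactors = FALSE)
    dip <- !is.na(cl$a2)
    two <- data.frame(sample_id = cl$sample_id[dip], sex = sx$sex[dip],
                      population = sx$population[dip], locus = cl$locus[dip],
                      allele = cl$a2[dip], stringsAsFactors = FALSE)
    out <- rbind(one, two)
    out <- out[order(match(out$sample_id, x$samples$sample_id),
                     match(out$locus, x$panel$locus), out$allele), ]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
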