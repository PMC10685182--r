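#' Run the full STR population workflow
#'
#' One call drives the study-shaped pipeline: obtain genotypes (simulation
#' or files), estimate allele frequencies for the cohort and the reference
#' population, compute per-locus and combined forensic parameters, HWE
#' exact tests, two-locus LD tests, pairwise F_ST with PCoA coordinates,
#' and the cognate/non-cognate RMP audit. Every stage draws its seed
#' deterministically from the root seed, so identical configurations yield
#' byte-identical outputs; each output is written to `<name>.partial`
#' first and renamed on success, so a failing stage leaves its partial
#' file behind and aborts with the stage name.
#'
#' @param config path to a YAML configuration or an equivalent list.
#'   Recognized fields:
#'   \describe{
#'     \item{`seed`}{root seed (integer).}
#'     \item{`output_dir`}{output directory.}
#'     \item{`simulate`}{list; `f` = per-subpopulation divergence of the
#'       bundled demo model. Mutually exclusive with `genotypes`.}
#'     \item{`genotypes`, `panel`, `dialect`}{paths for file input.}
#'     \item{`cohort`, `reference`}{population labels of the cohort and
#'       the non-cognate reference.}
#'     \item{`noncognate_frequencies`}{optional path to a reference
#'       frequency table (otherwise estimated from the `reference`
#'       population).}
#'     \item{`hwe`}{list: `dememorization`, `steps`.}
#'     \item{`ld`}{list: `pairs` (list of 2-vectors), `sex`, `n_perm`.}
#'     \item{`fst`}{list: `n_perm`.}
#'     \item{`audit`}{list: `f_list`.}
#'   }
#' @param output_dir overrides the configured output directory.
#' @return data.frame manifest (file, md5) invisibly; also written to
#'   `manifest.tsv`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- output_dir %||% config$output_dir %||% "strpop_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  outputs <- character(0)
  deliver <- function(write_fn, name) {
    tmp <- file.path(out_dir, paste0(name, ".partial"))
    write_fn(tmp)
    file.rename(tmp, file.path(out_dir, name))
    outputs <<- c(outputs, name)
  }
  stage <- function(name, code) {
    t0 <- Sys.time()
    res <- tryCatch(force(code), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    logmsg("stage %-10s done in %.1fs (seed %d)", name,
           as.numeric(difftime(Sys.time(), t0, units = "secs")),
           derive_seed(seed, name))
    res
  }

  # -- input ----------------------------------------------------------------
  tab <- stage("input", {
    if (!is.null(config$simulate)) {
      f <- config$simulate$f %||% 0.01
      model <- demo_model(f = f)
      if (!is.null(config$simulate$subpops)) {
        sp <- do.call(rbind, lapply(config$simulate$subpops, as.data.frame))
        model$subpops <- sp[c("name", "f", "n_male", "n_female")]
      }
      simulate_population(model, derive_seed(seed, "input"))
    } else {
      if (is.null(config$genotypes)) {
        stop("config needs either 'simulate' or 'genotypes'")
      }
      read_genotypes(config$genotypes, config$panel,
                     config$dialect %||% "wide")
    }
  })
  deliver(function(p) write_genotypes(tab, p), "genotypes.tsv")

  pops <- unique(tab$samples$population)
  cohort_pop <- config$cohort %||% pops[1]
  ref_pop <- config$reference %||% setdiff(pops, cohort_pop)[1]
  cohort <- subset_population(tab, cohort_pop)

  # -- frequencies ----------------------------------------------------------
  freqs <- stage("freqs", {
    cog <- frequencies_from_table(cohort, "pooled")
    non <- if (!is.null(config$noncognate_frequencies)) {
      read_frequencies(config$noncognate_frequencies, population = ref_pop)
    } else {
      frequencies_from_table(subset_population(tab, ref_pop), "pooled")
    }
    list(cognate = cog, noncognate = non)
  })
  deliver(function(p) write_frequencies(freqs$cognate, p),
          "cognate_freqs.tsv")
  deliver(function(p) write_frequencies(freqs$noncognate, p),
          "noncognate_freqs.tsv")

  # -- forensic parameters --------------------------------------------------
  stats_df <- stage("stats", forensic_summary(cohort))
  deliver(function(p) {
    comb <- attr(stats_df, "combined")
    df <- stats_df
    num <- vapply(df, is.numeric, logical(1))
    out <- df
    out[num] <- lapply(df[num], function(v) sprintf("%.4f", v))
    names(out)[num] <- paste0(names(df)[num], "_4dp")
    full <- df[num]
    names(full) <- paste0(names(df)[num], "_full")
    combined_line <- paste(sprintf("# combined %s = %.6g", names(comb),
                                   unlist(comb)), collapse = "\n")
    con <- file(p, "w", encoding = "UTF-8")
    writeLines(combined_line, con)
    utils::write.table(cbind(out, full), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }, "stats.tsv")

  # -- HWE ------------------------------------------------------------------
  hwe_df <- stage("hwe", {
    dem <- config$hwe$dememorization %||% 1e5
    stp <- config$hwe$steps %||% 1e6
    rows <- lapply(seq_len(nrow(tab$panel)), function(i) {
      lc <- tab$panel$locus[i]
      xlink <- tab$panel$chromosome[i] == "X"
      cl <- locus_calls(cohort, lc, if (xlink) "F" else "both")
      cl <- cl[!is.na(cl$a2), , drop = FALSE]
      g <- as.matrix(cl[c("a1", "a2")])
      res <- hwe_exact(g, dem, stp, seed = derive_seed(seed,
                                                       paste0("hwe", lc)))
      data.frame(locus = lc, chromosome = tab$panel$chromosome[i],
                 n = res$n, n_alleles = res$n_alleles, method = res$method,
                 p_value = res$p_value, mc_se = res$se,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$bonferroni_threshold <- round(as.numeric(bonferroni(0.05, nrow(df))),
                                     4)
    df
  })
  deliver(function(p) utils::write.table(hwe_df, p, sep = "\t",
                                         quote = FALSE, row.names = FALSE,
                                         fileEncoding = "UTF-8"), "hwe.tsv")

  # -- LD -------------------------------------------------------------------
  ld_df <- stage("ld", {
    pairs <- config$ld$pairs
    if (is.null(pairs)) {
      xl <- tab$panel$locus[tab$panel$chromosome == "X"]
      pairs <- list(c("DXS10079", "DXS6800"))
      pairs <- Filter(function(pr) all(pr %in% xl), pairs)
    }
    sex <- config$ld$sex %||% "M"
    n_perm <- config$ld$n_perm %||% 1000
    rows <- lapply(pairs, function(pr) {
      pr <- unlist(pr)
      res <- ld_test(tab, pr, sex = sex, n_perm = n_perm,
                     seed = derive_seed(seed, paste0("ld", pr[1], pr[2])))
      data.frame(locus1 = pr[1], locus2 = pr[2], sex = sex, n = res$n,
                 statistic = res$statistic, p_value = res$p_value,
                 n_perm = res$n_perm, stringsAsFactors = FALSE)
    })
    if (length(rows) == 0) NULL else do.call(rbind, rows)
  })
  if (!is.null(ld_df)) {
    deliver(function(p) utils::write.table(ld_df, p, sep = "\t",
                                           quote = FALSE, row.names = FALSE,
                                           fileEncoding = "UTF-8"), "ld.tsv")
  }

  # -- F_ST and PCoA --------------------------------------------------------
  fst_res <- stage("fst", pairwise_fst(tab,
                                       n_perm = config$fst$n_perm %||% 1000,
                                       seed = derive_seed(seed, "fst")))
  deliver(function(p) {
    m <- fst_res$fst
    df <- data.frame(population = rownames(m), m, check.names = FALSE)
    if (!is.null(fst_res$p_value)) {
      pm <- fst_res$p_value
      colnames(pm) <- paste0("p_", colnames(pm))
      df <- cbind(df, pm)
    }
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }, "fst.tsv")
  coords <- stage("pcoa", pcoa_coords(fst_res$fst))
  deliver(function(p) {
    df <- data.frame(population = rownames(coords$coordinates),
                     coords$coordinates, check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }, "coords.tsv")

  # -- RMP audit ------------------------------------------------------------
  audit <- stage("audit", {
    f_list <- unlist(config$audit$f_list %||% c(0, 0.0016, 0.0108, 0.0170))
    rmp_audit(cohort, freqs$cognate, freqs$noncognate, f_list = f_list)
  })
  deliver(function(p) utils::write.table(audit$table, p, sep = "\t",
                                         quote = FALSE, row.names = FALSE,
                                         fileEncoding = "UTF-8"),
          "audit.tsv")

  manifest <- data.frame(
    file = outputs,
    md5 = unname(tools::md5sum(file.path(out_dir, outputs))),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  logmsg("pipeline complete: %d outputs in %s", length(outputs), out_dir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
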