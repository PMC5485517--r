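#' Two-stage high-order interaction detection
#'
#' The main entry point: quality control (optional), stage-1 screening of all
#' SNP pairs ([screen()]) and stage-2 K-locus search ([run_stage2()]),
#' returning a classed result with the reported interactions, the screening
#' summary and the full effective configuration. With identical inputs and
#' `seed` the result is reproducible, including the stochastic ACO branch.
#'
#' @param x a [genotype_dataset()], or a file path (see `format`).
#' @param format input dialect when `x` is a path: `"tsv"` or `"pedmap"`.
#' @param alpha0 preset significance level (default 0.05).
#' @param omega intermediate-band scale factor (default `1e4`).
#' @param K interaction order to report (>= 3, default 3).
#' @param strategy stage-2 strategy: `"auto"` (exhaustive iff the candidate
#'   count W < 2000), `"exhaustive"` or `"aco"`.
#' @param aco optional list of [aco_config()] overrides (e.g.
#'   `list(n_ants = 500, rho = 0.05)`).
#' @param seed RNG seed used for the ACO branch.
#' @param qc apply [quality_control()] first (default `TRUE`).
#' @param thresholds [qc_thresholds()] used when `qc = TRUE`.
#' @return An object of class `episcreen_result`: list with `interactions`
#'   (data frame: SNP id and index columns, `chi2`, `df`, `p`,
#'   `bonferroni_level`, plus attribute-free `strategy` column), `screening`
#'   (the [screen()] result), `qc_report`, `config` and `log` (character
#'   vector of run records).
#' @export
episcreen <- function(x, format = c("tsv", "pedmap"), alpha0 = 0.05,
                      omega = 1e4, K = 3L, strategy = c("auto", "exhaustive",
                                                        "aco"),
                      aco = list(), seed = NULL, qc = TRUE,
                      thresholds = qc_thresholds()) {
  strategy <- match.arg(strategy)
  if (K < 3L) stop("interaction order K must be >= 3")
  if (is.character(x)) x <- read_genotypes(x, match.arg(format))
  stopifnot(inherits(x, "genotype_dataset"))
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  say("input: %d samples (%d cases, %d controls), %d SNPs",
      nrow(x$genotypes), x$n_case, x$n_control, ncol(x$genotypes))
  qc_report <- NULL
  if (qc) {
    qcr <- quality_control(x, thresholds)
    x <- qcr$dataset
    qc_report <- qcr$report
    say("QC removed %d entities; %d SNPs remain", nrow(qc_report),
        ncol(x$genotypes))
  }
  bits <- bit_encode(x)
  scr <- screen(x, alpha0 = alpha0, omega = omega, bits = bits)
  say("screening: W = %d candidates (%d significant, %d intermediate); %d strong-main-effect SNPs; LRT discarded %d",
      scr$W, scr$n_significant, scr$n_intermediate, length(scr$flagged),
      scr$n_lrt_discarded)
  config <- list(alpha0 = alpha0, omega = omega, K = as.integer(K),
                 strategy = strategy, seed = seed, qc = qc,
                 M = bits$M, aco = aco)
  if (scr$W == 0L) {
    say("candidate set empty after screening: nothing to search")
    inter <- empty_interactions(K)
    inter$strategy <- character(0)
    return(new_episcreen_result(inter, scr, qc_report, config, log, x))
  }
  will_aco <- strategy == "aco" ||
    (strategy == "auto" && scr$W >= 2000L)
  aco_cfg <- if (will_aco)
    do.call(aco_config, c(list(W = scr$W), aco,
                          if (is.null(aco$seed)) list(seed = seed)))
  res <- run_stage2(scr, bits, K = K, strategy = strategy, config = aco_cfg,
                    alpha0 = alpha0, M = bits$M)
  used <- attr(res, "strategy")
  say("stage 2 (%s): %d significant %d-locus interaction(s) at level %.4g",
      used, nrow(res), K, bonferroni_level(alpha0, bits$M, K))
  if (nrow(res)) res$strategy <- used else res$strategy <- character(0)
  # attach SNP ids alongside indices
  idc <- paste0("snp", seq_len(K))
  for (j in seq_len(K))
    res[[paste0("id", j)]] <- x$snp_ids[res[[idc[j]]]]
  new_episcreen_result(res, scr, qc_report, config, log, x)
}

new_episcreen_result <- function(interactions, screening, qc_report, config,
                                 log, dataset) {
  structure(list(interactions = interactions, screening = screening,
                 qc_report = qc_report, config = config, log = log,
                 snp_ids = dataset$snp_ids),
            class = "episcreen_result")
}

#' @export
print.episcreen_result <- function(x, ...) {
  cat("Two-stage high-order SNP interaction scan\n")
  for (l in x$log) cat(" ", l, "\n")
  if (nrow(x$interactions)) {
    cat("\nReported interactions:\n")
    print(utils::head(x$interactions, 10L))
    if (nrow(x$interactions) > 10L)
      cat(sprintf("  ... and %d more\n", nrow(x$interactions) - 10L))
  } else {
    cat("\nNo significant interactions reported.\n")
  }
  invisible(x)
}

#' @export
summary.episcreen_result <- function(object, ...) {
  s <- object$screening
  cat(sprintf(paste0("K = %d scan of M = %d SNPs: W = %d candidates ",
                     "(%d significant / %d intermediate), %d interactions ",
                     "reported\n"),
              object$config$K, object$config$M, s$W, s$n_significant,
              s$n_intermediate, nrow(object$interactions)))
  invisible(object)
}

#' @export
plot.episcreen_result <- function(x, ...) {
  cand <- x$screening$candidates
  if (!nrow(cand)) {
    warning("no retained pairs to plot")
    return(invisible(x))
  }
  graphics::hist(cand$chi2, breaks = 40,
                 main = "Retained pairwise chi-squared statistics",
                 xlab = expression(chi^2), ...)
  graphics::abline(v = x$screening$scheme$chi2_alpha, lty = 2)
  graphics::abline(v = x$screening$scheme$chi2_alpha_prime, lty = 3)
  invisible(x)
}

# deterministic polynomial hash of the serialized configuration
config_hash <- function(config) {
  s <- if (length(config))
    paste(deparse(config[order(names(config))]), collapse = "") else ""
  h <- 0
  for (x in utf8ToInt(s)) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write an interaction report as TSV
#'
#' Writes the reported interactions with a stable column order and
#' scientific-notation p-values, preceded by `#` comment lines carrying the
#' package version and a hash of the effective configuration. An empty
#' result yields a header-only file.
#'
#' @param result an `episcreen_result` (or a stage-2 data frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  if (inherits(result, "episcreen_result")) {
    df <- result$interactions
    cfg <- result$config
  } else {
    df <- result
    cfg <- list()
  }
  num <- vapply(df, is.numeric, logical(1)) &
    names(df) %in% c("chi2", "p", "bonferroni_level")
  fmt <- df
  for (j in which(num)) fmt[[j]] <- sprintf("%.6e", df[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# episcreen %s", as.character(packageVersion("episcreen"))),
               sprintf("# config_hash %s", config_hash(cfg)),
               sprintf("# config %s",
                       paste(names(cfg),
                             vapply(cfg, function(v)
                               paste(deparse(v), collapse = ""),
                               character(1)),
                             sep = "=", collapse = " "))),
             con)
  write.table(fmt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an interaction report
#'
#' @param path a file written by [write_report()].
#' @return The interactions data frame; header comments are returned in
#'   attribute `header`.
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) <= 1L) {
    cols <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                 cols))
  } else {
    df <- read.table(text = paste(body, collapse = "\n"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
  }
  attr(df, "header") <- hdr
  df
}
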