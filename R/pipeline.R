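# Pipeline orchestration: simulate -> preprocess -> spectra -> PAF ->
# EEG-age -> statistics -> report, driven by a single configuration
# object and a single top-level seed. Per-stage artefacts are written as
# plain-text tables plus a JSON manifest, and identical configurations
# reproduce identical outputs.

#' Pipeline configuration
#'
#' Defaults follow the reference analysis settings throughout: 500 Hz
#' sampling, Savitzky-Golay baseline 1025 points / order 3, +-120 uV
#' artifact threshold, 100 s target clean duration, AR order 256 on the
#' 0.1-45 Hz / 0.1 Hz grid, Welch 4096 ms Hamming window with 50%
#' overlap smoothed with a 5th-order / 11-bin filter, alpha band 7-13 Hz,
#' 1000 permutations for PLS factor selection, 25 PARAFAC replications,
#' and a JZS prior scale of 0.354.
#'
#' @param cohort A [cohort_spec()] describing the synthetic input.
#' @param stages Character vector of stages to run, in fixed order
#'   `simulate`, `preprocess`, `spectra`, `paf`, `eeg_age`, `stats`,
#'   `report`. Later stages require their upstream stages.
#' @param output_dir Directory for artefacts (`NULL` for none).
#' @param seed Top-level seed; every stage draw derives from it.
#' @param fs,artifact_threshold,target_seconds,max_drop,ar_order,n_starts
#'   Stage parameters (see the stage functions).
#' @param welch_window_ms,welch_overlap,sg_order,sg_window Welch settings.
#' @param alpha_band Alpha band in Hz.
#' @param n_perm,max_factors PLS factor-selection settings.
#' @param rpls_factors,tripls_factors Component counts for R-PLS and
#'   trilinear PLS.
#' @param parafac_scan Run the PARAFAC rank scan (off by default; the
#'   diagnostics are expensive and rank selection is an interactive
#'   judgement).
#' @param parafac_factors,parafac_replications Rank-scan settings.
#' @param r_scale JZS Bayes-factor prior scale.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       stages = c("simulate", "preprocess", "spectra",
                                  "paf", "eeg_age", "stats", "report"),
                       output_dir = NULL,
                       seed = 42L,
                       fs = 500,
                       artifact_threshold = 120,
                       target_seconds = 100,
                       max_drop = 16,
                       ar_order = 256L,
                       n_starts = 10,
                       welch_window_ms = 4096,
                       welch_overlap = 0.5,
                       sg_order = 5L,
                       sg_window = 11L,
                       alpha_band = c(7, 13),
                       n_perm = 1000,
                       max_factors = 10,
                       rpls_factors = 2,
                       tripls_factors = 3,
                       parafac_scan = FALSE,
                       parafac_factors = 1:10,
                       parafac_replications = 25,
                       r_scale = 0.354) {
  stopifnot(inherits(cohort, "cohort_spec"))
  all_stages <- c("simulate", "preprocess", "spectra", "paf", "eeg_age",
                  "stats", "report")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop_config("stages", paste("unknown:", bad[1]))
  cfg <- list(cohort = cohort, stages = intersect(all_stages, stages),
              output_dir = output_dir, seed = as.integer(seed), fs = fs,
              artifact_threshold = artifact_threshold,
              target_seconds = target_seconds, max_drop = max_drop,
              ar_order = as.integer(ar_order), n_starts = n_starts,
              welch_window_ms = welch_window_ms,
              welch_overlap = welch_overlap,
              sg_order = sg_order, sg_window = sg_window,
              alpha_band = alpha_band, n_perm = n_perm,
              max_factors = max_factors, rpls_factors = rpls_factors,
              tripls_factors = tripls_factors,
              parafac_scan = parafac_scan,
              parafac_factors = parafac_factors,
              parafac_replications = parafac_replications,
              r_scale = r_scale)
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in fixed order on a synthetic cohort. Per
#' participant: time-series synthesis, cleaning, AR channel spectra on
#' the cleaned common segment, SVD summarization, the five PAF
#' estimators; cohort level: PLS / R-PLS / trilinear PLS EEG-age models
#' and the statistics battery. Artefacts (cohort table, PAF table,
#' EEG-age table, statistics tables, manifest) are written to
#' `config$output_dir` when set.
#'
#' @param config A [run_config()].
#' @return Object of class `run_report` with per-stage results and a
#'   `manifest` describing parameters and stages run.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  stages <- config$stages
  res <- list(config = config)
  grid <- frequency_grid()

  if ("simulate" %in% stages) {
    cohort <- config$cohort
    cohort$seed <- config$seed
    res$cohort <- generate_cohort(cohort)
    res$cohort_table <- cohort_table(res$cohort)
  }

  need <- function(what, stage)
    if (is.null(res[[what]]))
      stop(sprintf("stage '%s' requires upstream results '%s'", stage, what),
           call. = FALSE)

  if (any(c("preprocess", "spectra", "paf") %in% stages)) {
    need("cohort", "preprocess")
    parts <- res$cohort$participants
    n <- length(parts)
    spec <- res$cohort$spec
    svd_spectra <- matrix(0, n, length(grid))
    chan_spectra <- vector("list", n)
    welch_smooth <- vector("list", n)
    clean_info <- vector("list", n)
    paf_rows <- list()
    for (i in seq_len(n)) {
      p <- parts[[i]]
      eeg <- synthesize_timeseries(
        p, duration_s = spec$recording_seconds, fs = config$fs,
        drift_amplitude = spec$drift_amplitude,
        artifact_rate = spec$artifact_rate,
        target_rms = spec$target_rms,
        seed = derive_seed(config$seed, i))
      cl <- clean_eeg(eeg, threshold = config$artifact_threshold,
                      target_seconds = config$target_seconds,
                      max_drop = config$max_drop)
      clean_info[[i]] <- data.frame(
        participant_id = p$participant_id,
        clean_seconds = cl$interval$length / cl$fs,
        n_dropped = length(cl$dropped_channels))
      if (!any(c("spectra", "paf") %in% stages)) next
      sp <- channel_log2_spectra(cl$segment, fs = cl$fs,
                                 order = config$ar_order, freq = grid)
      chan_spectra[[i]] <- sp
      sv <- svd_first_component(t(sp$values))
      svd_spectra[i, ] <- sv$component_spectrum
      if ("paf" %in% stages) {
        ws <- lapply(seq_len(nrow(cl$segment)), function(ci) {
          w <- welch_psd(cl$segment[ci, ], fs = cl$fs,
                         window_ms = config$welch_window_ms,
                         overlap = config$welch_overlap)
          normalize_and_smooth(w$power, w$freq, sg_order = config$sg_order,
                               sg_window = config$sg_window)
        })
        names(ws) <- rownames(cl$segment)
        welch_smooth[[i]] <- ws
        fitp <- fit_spectral_model(sv$component_spectrum, grid,
                                   n_starts = config$n_starts,
                                   seed = derive_seed(config$seed, 10000 + i))
        npaf <- naive_paf(sp, band = config$alpha_band)
        paf_rows[[i]] <- data.frame(
          participant_id = p$participant_id, age = p$age,
          n_paf = npaf$value,
          d_paf = direct_paf(sv, grid, config$alpha_band)$value,
          m_paf = modeled_paf(fitp)$value,
          c_paf = corcoran_paf(ws, alpha_band = config$alpha_band)$value,
          k_paf = klimesch_paf(ws, alpha_band = config$alpha_band)$value,
          adj_r2 = fitp$adj_r2)
        attr(paf_rows[[i]], "n_paf_per_channel") <- npaf$per_channel
      }
    }
    res$clean_summary <- do.call(rbind, clean_info)
    res$svd_spectra <- svd_spectra
    colnames(res$svd_spectra) <- sprintf("f%.1f", grid)
    res$channel_spectra <- chan_spectra
    if ("paf" %in% stages) {
      res$paf_table <- do.call(rbind, paf_rows)
      res$n_paf_channels <- do.call(rbind, lapply(paf_rows, function(r)
        attr(r, "n_paf_per_channel")))
      rownames(res$n_paf_channels) <- res$paf_table$participant_id
    }
  }

  if ("eeg_age" %in% stages) {
    need("svd_spectra", "eeg_age")
    ages <- res$cohort_table$age
    X <- res$svd_spectra
    sel <- select_factors_by_permutation(
      X, ages, max_factors = config$max_factors, n_perm = config$n_perm,
      seed = derive_seed(config$seed, 20001))
    nf <- max(sel$n_significant, 1)
    pls <- fit_pls(X, ages, nf)
    rpls <- rpls_select(X, ages, n_factors = config$rpls_factors)
    # tensor over the channels retained for every participant
    common <- Reduce(intersect, lapply(res$channel_spectra, function(s)
      colnames(s$values)))
    if (length(common) < 2)
      stop("fewer than 2 channels retained across all participants",
           call. = FALSE)
    tensor <- aperm(simplify2array(lapply(res$channel_spectra, function(s)
      s$values[, common, drop = FALSE])), c(3, 2, 1))
    tripls <- fit_tripls(tensor, ages, config$tripls_factors)
    res$eeg_age <- list(
      selection = sel, pls = pls, vip = vip_scores(pls), rpls = rpls,
      tripls = tripls,
      loocv = pls_loocv(X, ages, nf),
      table = data.frame(participant_id = res$cohort_table$participant_id,
                         age = ages,
                         pls_age = pls$fitted,
                         rpls_age = predict_age(
                           rpls$final_model,
                           X[, rpls$selected, drop = FALSE]),
                         tripls_age = tripls$fitted))
    if (isTRUE(config$parafac_scan))
      res$parafac <- parafac_rank_scan(
        tensor, factors = config$parafac_factors,
        n_replications = config$parafac_replications,
        seed = derive_seed(config$seed, 20002))
  }

  if ("stats" %in% stages) {
    need("paf_table", "stats")
    res$stats <- compute_statistics(res, config)
  }

  res$manifest <- list(
    package_version = as.character(utils::packageVersion("eegage")),
    seed = config$seed,
    stages = stages,
    n_participants = if (!is.null(res$cohort)) length(res$cohort$participants)
                     else NA,
    parameters = config[setdiff(names(config), c("cohort", "stages",
                                                 "output_dir"))],
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if ("report" %in% stages && !is.null(config$output_dir))
    write_report(res, config$output_dir)
  class(res) <- "run_report"
  res
}

# The cohort-level comparison battery: brain-age regressions for every
# method, the 7x7 correlation matrix, Bland-Altman grids, paired tests,
# dependent-correlation comparisons against age, MINQUE on the
# channel-wise N-PAF grid, demographics correlations and Bayes factors.
compute_statistics <- function(res, config) {
  tab <- res$paf_table
  ages <- tab$age
  out <- list()

  paf_methods <- c(d_paf = "D", m_paf = "M", c_paf = "C", k_paf = "K")
  brain_age <- data.frame(row.names = tab$participant_id)
  paf_fits <- list()
  for (col in names(paf_methods)) {
    ok <- !is.na(tab[[col]])
    if (sum(ok) < 4 || sd(tab[[col]][ok]) == 0) {
      brain_age[[paste0(col, "_age")]] <- rep(NA_real_, nrow(tab))
      next
    }
    fit <- linreg_rmse(tab[[col]][ok], ages[ok])
    paf_fits[[col]] <- data.frame(
      method = paf_methods[[col]], slope = unname(fit$coefficients[2]),
      intercept = unname(fit$coefficients[1]), r = fit$r * sign(fit$coefficients[2]),
      rmse = fit$rmse, n = fit$n)
    pred <- rep(NA_real_, nrow(tab))
    pred[ok] <- fit$fitted
    brain_age[[paste0(col, "_age")]] <- pred
  }
  out$paf_age_regressions <- do.call(rbind, paf_fits)
  # the reverse regression: PAF on age (slope in Hz/year)
  okm <- !is.na(tab$m_paf)
  if (sum(okm) >= 4) {
    mfit <- linreg_rmse(ages[okm], tab$m_paf[okm])
    out$mpaf_on_age <- data.frame(slope = unname(mfit$coefficients[2]),
                                  intercept = unname(mfit$coefficients[1]),
                                  rmse = mfit$rmse)
  }

  if (!is.null(res$eeg_age)) {
    ea <- res$eeg_age$table
    brain_age$pls_age <- ea$pls_age
    brain_age$rpls_age <- ea$rpls_age
    brain_age$tripls_age <- ea$tripls_age
  }
  out$brain_age <- cbind(data.frame(participant_id = tab$participant_id,
                                    age = ages), brain_age)

  est_cols <- c("d_paf", "m_paf", "c_paf", "k_paf")
  ba_rows <- list()
  for (i in seq_along(est_cols)) for (j in seq_along(est_cols)) {
    if (i >= j) next
    if (sum(complete.cases(tab[[est_cols[i]]], tab[[est_cols[j]]])) < 3)
      next
    ba <- bland_altman(tab[[est_cols[i]]], tab[[est_cols[j]]])
    tt <- paired_t(tab[[est_cols[i]]], tab[[est_cols[j]]])
    ba_rows[[length(ba_rows) + 1]] <- data.frame(
      a = est_cols[i], b = est_cols[j], bias = ba$bias, sd_diff = ba$sd_diff,
      loa_low = ba$loa_low, loa_high = ba$loa_high,
      proportional_slope = ba$proportional_slope,
      t = tt$t, p = tt$p)
  }
  out$bland_altman <- if (length(ba_rows)) do.call(rbind, ba_rows) else NULL

  ba_cols <- setdiff(names(brain_age), c("participant_id", "age"))
  vals <- cbind(tab[est_cols],
                brain_age[setdiff(ba_cols, paste0(est_cols, "_age"))])
  cm <- suppressWarnings(cor(vals, use = "pairwise.complete.obs"))
  out$method_correlations <- cm

  # dependent-correlation comparisons of each pair of brain-age estimates
  # against chronological age
  gh_rows <- list()
  for (i in seq_along(vals)) for (j in seq_along(vals)) {
    if (i >= j) next
    ok <- !is.na(vals[[i]]) & !is.na(vals[[j]])
    if (sum(ok) < 4) next
    cmp <- tryCatch(compare_dependent_correlations(
      abs(cor(vals[[i]][ok], ages[ok])), abs(cor(vals[[j]][ok], ages[ok])),
      abs(cor(vals[[i]][ok], vals[[j]][ok])), sum(ok)),
      error = function(e) NULL)
    if (is.null(cmp)) next
    gh_rows[[length(gh_rows) + 1]] <- data.frame(
      a = names(vals)[i], b = names(vals)[j],
      diff = cmp$r13 - cmp$r23, t = cmp$t_stat, df = cmp$df, p = cmp$p)
  }
  out$correlation_comparisons <- do.call(rbind, gh_rows)

  if (!is.null(res$n_paf_channels) && ncol(res$n_paf_channels) >= 2) {
    vc <- tryCatch(minque_components(res$n_paf_channels),
                   error = function(e) NULL)
    if (!is.null(vc)) out$variance_components <- vc
  }

  ct <- res$cohort_table
  demo <- list(
    nart_iq_age = pearson(ct$nart_iq, ct$age),
    qmci_age = pearson(ct$qmci, ct$age))
  out$demographics <- data.frame(
    pair = names(demo),
    r = vapply(demo, `[[`, 0, "r"),
    p = vapply(demo, `[[`, 0, "p"))

  if (!is.null(res$eeg_age) &&
      sum(complete.cases(brain_age$m_paf_age, brain_age$pls_age)) >
        length(est_cols) + 6) {
    okm <- complete.cases(brain_age$m_paf_age, brain_age$pls_age)
    bf_age <- jzs_regression_bf01(
      ages[okm], brain_age$pls_age[okm],
      cbind(brain_age$pls_age, brain_age$m_paf_age)[okm, ],
      r_scale = config$r_scale)
    out$bayes_factors <- data.frame(
      comparison = "age ~ pls_age vs age ~ pls_age + m_paf_age",
      bf01 = bf_age$bf01)
    ctrl <- tab[okm, c("m_paf", "d_paf", "c_paf", "k_paf")]
    okc <- complete.cases(ctrl)
    pc <- tryCatch(partial_correlation(brain_age$pls_age[okm][okc],
                                       ages[okm][okc], ctrl[okc, ]),
                   error = function(e) NULL)
    if (!is.null(pc))
      out$pls_partial <- data.frame(r = pc$r, p = pc$p, df = pc$df)
  }
  out
}

#' Write pipeline artefacts
#'
#' Emits the cohort table, per-method PAF table, EEG-age table, the
#' statistics tables (correlation matrix, Bland-Altman grid, variance
#' components, Bayes factors) as CSV, and the manifest plus model
#' summaries as JSON.
#'
#' @param res A `run_report` (or the result list of [run_analysis()]).
#' @param dir Output directory (created when absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(res, dir) {
  if (is.null(res$cohort) || length(res$cohort$participants) == 0)
    stop("nothing to report: empty cohort", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(obj, name) {
    p <- file.path(dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(res$cohort_table, "cohort.csv")
  if (!is.null(res$clean_summary)) wr(res$clean_summary, "clean_summary.csv")
  if (!is.null(res$paf_table)) wr(res$paf_table, "paf_table.csv")
  if (!is.null(res$eeg_age)) wr(res$eeg_age$table, "eeg_age.csv")
  if (!is.null(res$stats)) {
    st <- res$stats
    if (!is.null(st$paf_age_regressions))
      wr(st$paf_age_regressions, "paf_age_regressions.csv")
    if (!is.null(st$bland_altman)) wr(st$bland_altman, "bland_altman.csv")
    wr(as.data.frame(st$method_correlations), "method_correlations.csv")
    if (!is.null(st$correlation_comparisons))
      wr(st$correlation_comparisons, "correlation_comparisons.csv")
    if (!is.null(st$variance_components))
      wr(data.frame(component = names(st$variance_components$raw),
                    estimate = st$variance_components$raw,
                    proportion = st$variance_components$proportions),
         "variance_components.csv")
    if (!is.null(st$bayes_factors)) wr(st$bayes_factors, "bayes_factors.csv")
    wr(st$demographics, "demographics.csv")
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(res$manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE, digits = NA)
  invisible(c(paths, mp))
}

#' Read raw EEG from a delimited text file
#'
#' Expected format: a first line `fs=<Hz>` followed by one line per
#' channel, tab-separated, with the channel label in the first field and
#' the samples (microvolts) after it — the format written by
#' [write_eeg()].
#'
#' @param path File path.
#' @return A [raw_eeg()].
#' @export
read_eeg <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("^fs=", header))
    stop(sprintf("malformed EEG file '%s': first line must be 'fs=<Hz>'",
                 path), call. = FALSE)
  fs <- as.numeric(sub("^fs=", "", header))
  if (!is.finite(fs) || fs <= 0)
    stop(sprintf("malformed EEG file '%s': unparseable sampling rate '%s'",
                 path, header), call. = FALSE)
  dt <- data.table::fread(path, skip = 1, header = FALSE, sep = "\t")
  labels <- as.character(dt[[1]])
  mat <- as.matrix(dt[, -1])
  if (anyNA(mat))
    stop(sprintf(
      "malformed EEG file '%s': non-numeric or ragged sample fields", path),
      call. = FALSE)
  dimnames(mat) <- list(labels, NULL)
  raw_eeg(mat, fs = fs, labels = labels)
}

#' Write raw EEG to a delimited text file
#'
#' @param raw A [raw_eeg()].
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_eeg <- function(raw, path) {
  stopifnot(inherits(raw, "raw_eeg"))
  writeLines(sprintf("fs=%.10g", raw$fs), path)
  dt <- data.table::data.table(label = raw$labels)
  dt <- cbind(dt, data.table::as.data.table(raw$data))
  data.table::fwrite(dt, path, sep = "\t", append = TRUE,
                     col.names = FALSE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("eegage run report\n")
  cat("  stages:", paste(x$manifest$stages, collapse = ", "), "\n")
  if (!is.null(x$paf_table))
    cat(sprintf("  participants: %d, mean M-PAF %.2f Hz\n",
                nrow(x$paf_table), mean(x$paf_table$m_paf, na.rm = TRUE)))
  invisible(x)
}
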