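#' Full statistical summary of a per-vocalization feature table
#'
#' Reproduces the study's analysis surface from any S1-compatible table:
#' assignment counts and per-sex fractions, per-session counts with the
#' male-female count correlation and Mann-Whitney test, pooled per-sex
#' feature medians/IQRs with Mann-Whitney tests, per-animal medians with
#' Mann-Whitney tests, context-conditioned bandwidth/slope comparisons,
#' context vocalization counts, the high/low vocalizer split, and the
#' Monte-Carlo index distribution per feature.
#'
#' @param table a [feature_table].
#' @param n_samples,sample_size Monte-Carlo settings (skipped when either
#'   sex has fewer than `sample_size` assigned signals).
#' @param split_threshold high/low vocalizer threshold on male counts.
#' @param seed RNG seed for the Monte-Carlo sampling.
#' @return a list of data frames / objects (class `usv_summary`).
#' @export
summarize_feature_table <- function(table, n_samples = 1000,
                                    sample_size = 500,
                                    split_threshold = 2200, seed = NULL) {
  sex <- emitter_sex(table$emitter)
  assigned <- table[!is.na(sex), ]
  sex_a <- sex[!is.na(sex)]

  counts <- list(
    n_total = nrow(table),
    n_assigned = nrow(assigned),
    n_male = sum(sex_a == "male"),
    n_female = sum(sex_a == "female")
  )
  counts$male_fraction_pct <- 100 * counts$n_male / counts$n_assigned

  # per-session per-sex counts
  sess <- sort(unique(assigned$session_id))
  per_session <- data.frame(
    session_id = sess,
    male = vapply(sess, function(s)
      sum(assigned$session_id == s & sex_a == "male"), 1),
    female = vapply(sess, function(s)
      sum(assigned$session_id == s & sex_a == "female"), 1)
  )
  session_count_test <- if (nrow(per_session) >= 1 &&
                            all(per_session$male + per_session$female > 0)) {
    mann_whitney(per_session$male, per_session$female)
  } else NULL
  count_correlation <- if (nrow(per_session) >= 3) {
    pearson_cor(per_session$male, per_session$female)
  } else NULL

  features <- feature_numeric_columns
  pooled <- lapply(features, function(f) {
    m <- assigned[[f]][sex_a == "male"]
    fe <- assigned[[f]][sex_a == "female"]
    if (!sum(is.finite(m)) || !sum(is.finite(fe))) return(NULL)
    mann_whitney(m, fe)
  })
  names(pooled) <- features

  per_animal <- lapply(features, function(f) {
    pm <- per_animal_medians(assigned, f)
    test <- if (sum(pm$sex == "male", na.rm = TRUE) >= 1 &&
                sum(pm$sex == "female", na.rm = TRUE) >= 1) {
      mann_whitney(pm$median[pm$sex == "male"],
                   pm$median[pm$sex == "female"])
    } else NULL
    list(medians = pm, test = test)
  })
  names(per_animal) <- features

  by_context <- list()
  for (f in c("bandwidth_hz", "slope_hz_per_s")) {
    for (ctx in c("not_close", "followed", "following")) {
      m <- assigned[[f]][sex_a == "male" & assigned$context %in% ctx]
      fe <- assigned[[f]][sex_a == "female" & assigned$context %in% ctx]
      if (sum(is.finite(m)) >= 1 && sum(is.finite(fe)) >= 1) {
        by_context[[paste(f, ctx, sep = ".")]] <- mann_whitney(m, fe)
      }
    }
  }

  ctx_counts <- context_table(assigned)

  male_counts <- stats::setNames(per_session$male, per_session$session_id)
  split <- vocalizer_split(male_counts, split_threshold)

  mc <- NULL
  if (counts$n_male >= sample_size && counts$n_female >= sample_size) {
    mc <- lapply(features, function(f) {
      monte_carlo_index(assigned, f, n_samples, sample_size, seed = seed)
    })
    names(mc) <- features
  }

  normality <- lapply(features, function(f) {
    v <- assigned[[f]][is.finite(assigned[[f]])]
    if (length(v) >= 10) ks_nongaussian(v) else NULL
  })
  names(normality) <- features

  structure(list(counts = counts, per_session = per_session,
                 session_count_test = session_count_test,
                 count_correlation = count_correlation,
                 pooled = pooled, per_animal = per_animal,
                 by_context = by_context, context_counts = ctx_counts,
                 vocalizer_split = split, monte_carlo = mc,
                 normality = normality),
            class = "usv_summary")
}

#' @export
print.usv_summary <- function(x, ...) {
  c0 <- x$counts
  cat(sprintf("USV summary: %d signals, %d assigned (%.1f%% male)\n",
              c0$n_total, c0$n_assigned, c0$male_fraction_pct))
  if (!is.null(x$pooled$bandwidth_hz)) {
    b <- x$pooled$bandwidth_hz
    cat(sprintf("  pooled bandwidth: male %.2f kHz vs female %.2f kHz (p = %.3g)\n",
                b$median1 / 1000, b$median2 / 1000, b$p))
  }
  if (!is.null(x$monte_carlo)) {
    for (f in names(x$monte_carlo)) {
      m <- x$monte_carlo[[f]]
      cat(sprintf("  index %-15s %4d male-driven / %4d female-driven\n",
                  f, m$n_positive, m$n_negative))
    }
  }
  invisible(x)
}
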