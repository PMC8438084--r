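#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 113) # 4.4e-4 to two significant figures
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1, m == as.integer(m))
  alpha / m
}

#' Number of unordered pairs among k items
#'
#' @param k Non-negative integer.
#' @return `k * (k - 1) / 2`.
#' @examples
#' count_pairs(22) # 231
#' @export
count_pairs <- function(k) {
  stopifnot(k >= 0, k == as.integer(k))
  as.integer(k * (k - 1) / 2)
}

check_columns <- function(annotation, cols) {
  missing_cols <- setdiff(cols, names(annotation))
  if (length(missing_cols)) {
    abort(sprintf("Column(s) not in the annotation: %s",
                  paste(missing_cols, collapse = ", ")))
  }
}

#' Single-TF enrichment test
#'
#' Fits the one-annotation model: the slope on the binding indicator is the
#' mean chi-square difference between bound and unbound variants, tested by a
#' Wald z-test with an LD-block random intercept absorbing local dependence.
#'
#' @param variants Variant tibble with `chi2` and `block_id`.
#' @param annotation Binary annotation tibble aligned to `variants`.
#' @param tf Column name of the TF indicator.
#' @param ... Passed to [fit_block_lmm()].
#' @return A `block_lmm` fit; the `tf` term's estimate is \eqn{\Delta\bar\chi^2}.
#' @export
test_single_tf <- function(variants, annotation, tf, ...) {
  check_columns(annotation, tf)
  X <- tibble(!!tf := as.numeric(annotation[[tf]]))
  fit_block_lmm(variants$chi2, X, variants$block_id, ...)
}

#' All-TF association scan
#'
#' Convenience wrapper running [test_single_tf()] for every `tf`-kind column
#' and collecting one tidy row per TF.
#'
#' @inheritParams test_single_tf
#' @param tf_cols Columns to scan (default: all `tf`-kind columns).
#' @return Tibble with `tf_name`, `delta_chi2`, `std_error`, `statistic`,
#'   `p_value`, `var_block`, `var_resid`, `n_bound`, `low_support`.
#' @export
test_all_tfs <- function(variants, annotation, tf_cols = NULL, ...) {
  kind <- attr(annotation, "feature_kind")
  if (is.null(tf_cols)) {
    tf_cols <- if (!is.null(kind)) names(kind)[kind == "tf"] else names(annotation)
  }
  purrr::map_dfr(tf_cols, function(tf) {
    fit <- test_single_tf(variants, annotation, tf, ...)
    row <- dplyr::filter(tidy(fit), .data$term == tf)
    tibble(tf_name = tf, delta_chi2 = row$estimate, std_error = row$std_error,
           statistic = row$statistic, p_value = row$p_value,
           var_block = fit$var_block, var_resid = fit$var_resid,
           n_bound = sum(annotation[[tf]] == 1), low_support = row$low_support)
  })
}

#' Pairwise TF co-occupancy interaction test
#'
#' Fits the two-TF model with main effects and their product; the interaction
#' coefficient measures super- or sub-additivity of co-binding on the variant
#' chi-square scale. Also reports the three non-reference occupancy-group
#' contrasts (only TF1, only TF2, both) against the unbound group.
#'
#' @inheritParams test_single_tf
#' @param tf1,tf2 Column names of the two TF indicators.
#' @return A `block_lmm` fit with extra elements `degenerate` (TRUE when an
#'   occupancy cell of the 2x2 table is empty), `occupancy_table`, and
#'   `group_contrasts` (tibble of estimate/se/z/p for only-tf1, only-tf2, both).
#' @export
test_pairwise_interaction <- function(variants, annotation, tf1, tf2, ...) {
  check_columns(annotation, c(tf1, tf2))
  a1 <- as.numeric(annotation[[tf1]]); a2 <- as.numeric(annotation[[tf2]])
  occ <- table(factor(a1, levels = 0:1), factor(a2, levels = 0:1),
               dnn = c(tf1, tf2))
  degenerate <- any(occ == 0)
  if (degenerate) {
    warn("Degenerate design: at least one cell of the 2x2 occupancy table is empty.")
  }
  inter <- paste0(tf1, ":", tf2)
  X <- tibble(!!tf1 := a1, !!tf2 := a2, !!inter := a1 * a2)
  fit <- fit_block_lmm(variants$chi2, X, variants$block_id, ...)
  idx <- match(c(tf1, tf2, inter), fit$coefficients$term)
  b <- fit$coefficients$estimate
  V <- fit$vcov[idx, idx, drop = FALSE]
  # contrast rows on (b1, b2, b3)
  Cmat <- rbind(only_tf1 = c(1, 0, 0), only_tf2 = c(0, 1, 0), both = c(1, 1, 1))
  est <- drop(Cmat %*% b[idx])
  se <- sqrt(diag(Cmat %*% V %*% t(Cmat)))
  fit$group_contrasts <- tibble(
    group = rownames(Cmat), estimate = est, std_error = se,
    statistic = est / se, p_value = 2 * pnorm(-abs(est / se)))
  fit$occupancy_table <- occ
  fit$degenerate <- degenerate
  fit
}

joint_wald <- function(fit, terms) {
  idx <- match(terms, fit$coefficients$term)
  if (anyNA(idx)) abort("Unknown term(s) in joint Wald test.")
  b <- fit$coefficients$estimate[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  stat <- drop(crossprod(b, solve(V, b)))
  tibble(statistic = stat, df = length(idx),
         p_value = pchisq(stat, df = length(idx), lower.tail = FALSE))
}

#' Stratified interaction test
#'
#' Tests whether an enrichment effect differs between variants inside and
#' outside a binary stratifier annotation (e.g. binding by a pioneer factor).
#' Fits the effect model separately within each stratum and a pooled model
#' with all stratifier interactions; the highest-order interaction term (or a
#' joint Wald test when there are several) gives the interaction p-value.
#'
#' @inheritParams test_single_tf
#' @param stratifier Column name of the binary stratifying annotation.
#' @param terms Character vector of one or two annotation column names whose
#'   effect is compared across strata, or a numeric vector (e.g. a TF score)
#'   aligned to `variants`.
#' @return List with `strata` (named list of `block_lmm` fits for stratum
#'   `"0"` and `"1"`), `pooled` (`block_lmm`), and `interaction` (tibble with
#'   the interaction term(s), statistic and `p_value`).
#' @export
test_stratified_interaction <- function(variants, annotation, stratifier, terms,
                                        ...) {
  check_columns(annotation, stratifier)
  s <- as.numeric(annotation[[stratifier]])
  if (!all(s %in% c(0, 1))) abort("`stratifier` must be a binary column.")
  if (is.numeric(terms)) {
    stopifnot(length(terms) == nrow(variants))
    term_tab <- tibble(score = as.numeric(terms))
  } else {
    check_columns(annotation, terms)
    term_tab <- as_tibble(purrr::map(setNames(terms, terms),
                                     ~ as.numeric(annotation[[.x]])))
    if (length(terms) == 2) {
      term_tab[[paste0(terms[1], ":", terms[2])]] <-
        term_tab[[1]] * term_tab[[2]]
    }
  }
  for (lev in c(0, 1)) {
    if (!any(s == lev)) abort(sprintf("Stratum %d is empty.", lev))
  }
  strata <- purrr::map(setNames(c(0, 1), c("0", "1")), function(lev) {
    keep <- s == lev
    fit_block_lmm(variants$chi2[keep], term_tab[keep, , drop = FALSE],
                  variants$block_id[keep], ...)
  })
  pooled_X <- dplyr::bind_cols(
    term_tab,
    tibble(!!stratifier := s),
    as_tibble(purrr::map(setNames(names(term_tab),
                                  paste0(names(term_tab), ":", stratifier)),
                         ~ term_tab[[.x]] * s)))
  pooled <- fit_block_lmm(variants$chi2, pooled_X, variants$block_id, ...)
  int_terms <- paste0(names(term_tab), ":", stratifier)
  top <- int_terms[length(int_terms)] # highest-order term
  row <- dplyr::filter(tidy(pooled), .data$term == top)
  interaction <- tibble(term = top, estimate = row$estimate,
                        std_error = row$std_error, statistic = row$statistic,
                        p_value = row$p_value)
  if (length(int_terms) > 1) {
    jw <- joint_wald(pooled, int_terms)
    interaction$joint_statistic <- jw$statistic
    interaction$joint_df <- jw$df
    interaction$joint_p_value <- jw$p_value
  }
  list(strata = strata, pooled = pooled, interaction = interaction)
}

#' TF-score trend test
#'
#' Association of the per-variant TF-occupancy score with the chi-square
#' statistic: continuous mode fits a linear trend (slope per additional bound
#' TF); categorical mode fits per-category contrasts against the zero-score
#' category.
#'
#' @inheritParams test_single_tf
#' @param score Tibble from [compute_tf_score()] (columns `score`, `category`).
#' @param as_ `"continuous"` or `"categorical"`.
#' @return A `block_lmm` fit.
#' @export
test_score_trend <- function(variants, score, as_ = c("continuous", "categorical"),
                             ...) {
  as_ <- match.arg(as_)
  if (as_ == "continuous") {
    X <- tibble(score = as.numeric(score$score))
  } else {
    cat <- droplevels(score$category)
    ref <- levels(cat)[1]
    X <- as_tibble(purrr::map(
      setNames(levels(cat)[-1], paste0("score_", levels(cat)[-1])),
      ~ as.numeric(cat == .x)))
    attr(X, "reference") <- ref
  }
  fit_block_lmm(variants$chi2, X, variants$block_id, ...)
}

#' Chromatin-state association and TF-score interaction test
#'
#' Contrasts each chromatin state against a reference state (quiescent/low by
#' default); optionally adds TF-score categories and state-by-score
#' interaction terms, with a joint Wald chi-square test of all interaction
#' coefficients.
#'
#' @inheritParams test_single_tf
#' @param chromatin Annotation tibble from [annotate_chromatin()].
#' @param reference_state State mnemonic used as reference (default "Quies").
#' @param score_categories Optional factor/character of TF-score categories
#'   (from [compute_tf_score()]`$category`) to interact with states.
#' @return A `block_lmm` fit; when `score_categories` is given, extra elements
#'   `interaction_terms` and `interaction_joint` (tibble with the joint Wald
#'   statistic, df, `p_value`).
#' @export
test_chromatin_features <- function(variants, chromatin,
                                    reference_state = "Quies",
                                    score_categories = NULL, ...) {
  states <- levels(chromatin$state)
  if (!reference_state %in% states) {
    abort(sprintf("Reference state '%s' not among observed states (%s).",
                  reference_state, paste(states, collapse = ", ")))
  }
  non_ref <- setdiff(states, reference_state)
  X <- as_tibble(purrr::map(setNames(non_ref, paste0("state_", non_ref)),
                            ~ as.numeric(chromatin$state == .x)))
  if (is.null(score_categories)) {
    return(fit_block_lmm(variants$chi2, X, variants$block_id, ...))
  }
  sc <- droplevels(factor(score_categories))
  sc_ref <- levels(sc)[1]
  sc_cols <- setNames(levels(sc)[-1], paste0("score_", levels(sc)[-1]))
  Xs <- as_tibble(purrr::map(sc_cols, ~ as.numeric(sc == .x)))
  inter <- list()
  for (st in names(X)) for (sl in names(Xs)) {
    inter[[paste0(st, ":", sl)]] <- X[[st]] * Xs[[sl]]
  }
  full_X <- dplyr::bind_cols(X, Xs, as_tibble(inter))
  fit <- fit_block_lmm(variants$chi2, full_X, variants$block_id, ...)
  fit$interaction_terms <- names(inter)
  fit$interaction_joint <- joint_wald(fit, names(inter))
  fit
}
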