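#' Factorial ANOVA on item-level recovery error
#'
#' Between-subjects factorial ANOVA of per-item RMSE on sample size, test
#' length and node (all as factors, full interactions). Sums of squares are
#' Type II (via \code{car::Anova}), robust to the unbalanced item counts
#' across test lengths; partial eta-squared is
#' \code{SS_effect / (SS_effect + SS_residual)}. Factors observed at a
#' single level are dropped from the model with a warning.
#'
#' @param detail data.frame from \code{\link{recovery_detail}} with columns
#'   \code{N}, \code{J}, \code{node} and the RMSE columns.
#' @param response which RMSE to analyse: discrimination (\code{"alpha"}) or
#'   intercept (\code{"d"}).
#' @return An object of class \code{mpp_anova}: list with \code{table}
#'   (effect, sum_sq, df, F, p, eta_sq_partial), \code{residual_ss},
#'   \code{residual_df}, \code{response}, \code{model} (the underlying
#'   \code{lm}).
#' @export
factorial_anova <- function(detail, response = c("alpha", "d")) {
  response <- match.arg(response)
  y <- detail[[paste0(response, "_rmse")]]
  if (is.null(y)) stop("detail lacks the requested RMSE column")
  dat <- data.frame(rmse = y,
                    N = factor(detail$N),
                    J = factor(detail$J),
                    node = factor(detail$node, levels = MPP_NODES))
  terms_use <- c("N", "J", "node")
  single <- vapply(dat[terms_use], function(f) nlevels(droplevels(f)) < 2L,
                   logical(1))
  if (any(single)) {
    warning("factor(s) with a single level omitted: ",
            paste(terms_use[single], collapse = ", "))
    terms_use <- terms_use[!single]
  }
  if (!length(terms_use)) stop("no factor varies; ANOVA undefined")
  form <- stats::as.formula(paste("rmse ~", paste(terms_use, collapse = " * ")))
  fit <- stats::lm(form, data = dat)
  # car refuses exactly-zero residual variance; those degenerate fits are
  # balanced corner cases where sequential SS coincide with Type II
  a2 <- tryCatch(car::Anova(fit, type = 2),
                 error = function(e) suppressWarnings(stats::anova(fit)))
  tab <- as.data.frame(a2)
  res_row <- rownames(tab) == "Residuals"
  residual_ss <- tab$`Sum Sq`[res_row]
  residual_df <- tab$Df[res_row]
  eff <- tab[!res_row, , drop = FALSE]
  # snap floating-point dust to zero so degenerate fits report eta^2 = 0
  tol <- 1e-12 * max(sum(abs(tab$`Sum Sq`)), 1)
  if (residual_ss < tol) residual_ss <- 0
  ss <- ifelse(eff$`Sum Sq` < tol, 0, eff$`Sum Sq`)
  out <- data.frame(effect = rownames(eff),
                    sum_sq = ss,
                    df = eff$Df,
                    F = eff$`F value`,
                    p = eff$`Pr(>F)`,
                    eta_sq_partial = ifelse(ss <= 0, 0,
                      ss / (ss + residual_ss)),
                    row.names = NULL)
  structure(list(table = out, residual_ss = residual_ss,
                 residual_df = residual_df, response = response,
                 model = fit),
            class = "mpp_anova")
}

#' @export
print.mpp_anova <- function(x, digits = 3, ...) {
  cat(sprintf("Factorial ANOVA on %s RMSE (Type II SS)\n", x$response))
  tab <- x$table
  tab$sum_sq <- signif(tab$sum_sq, digits)
  tab$F <- signif(tab$F, digits)
  tab$p <- signif(tab$p, digits)
  tab$eta_sq_partial <- round(tab$eta_sq_partial, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("Residuals: SS %.4g on %d df\n", x$residual_ss, x$residual_df))
  invisible(x)
}

#' Pairwise simple-effects contrasts between nodes
#'
#' Pairwise t statistics comparing node mean RMSEs, either overall or within
#' each test length, using the pooled residual variance and residual degrees
#' of freedom of the full factorial model (504 at the full study design:
#' 540 item-level observations minus 36 cells). Contrasts are ordered
#' earlier-node-minus-later-node, so error growing down the decision
#' hierarchy yields negative t values.
#'
#' @param detail data.frame from \code{\link{recovery_detail}}.
#' @param response \code{"alpha"} or \code{"d"}.
#' @param within \code{"overall"} for node contrasts pooled over the design,
#'   or \code{"J"} for node contrasts within each test length.
#' @param adjust p-value adjustment across the reported contrasts:
#'   \code{"none"} (default), \code{"bonferroni"} or \code{"holm"}.
#' @return data.frame: grouping columns, \code{contrast}, \code{estimate}
#'   (difference of means), \code{t}, \code{df}, \code{p}.
#' @export
pairwise_simple_effects <- function(detail, response = c("alpha", "d"),
                                    within = c("overall", "J"),
                                    adjust = c("none", "bonferroni", "holm")) {
  response <- match.arg(response)
  within <- match.arg(within)
  adjust <- match.arg(adjust)
  an <- factorial_anova(detail, response)
  mse <- an$residual_ss / an$residual_df
  df <- an$residual_df
  y <- detail[[paste0(response, "_rmse")]]
  node <- factor(detail$node, levels = MPP_NODES)
  pairs <- list(c("midpoint", "agreement"),
                c("midpoint", "extreme"),
                c("agreement", "extreme"))
  one_group <- function(sel, label) {
    do.call(rbind, lapply(pairs, function(pr) {
      i1 <- sel & node == pr[1L]; i2 <- sel & node == pr[2L]
      n1 <- sum(i1); n2 <- sum(i2)
      if (!n1 || !n2)
        stop(sprintf("empty group for contrast %s - %s", pr[1L], pr[2L]))
      est <- mean(y[i1]) - mean(y[i2])
      tval <- est / sqrt(mse * (1 / n1 + 1 / n2))
      data.frame(group = label,
                 contrast = paste(pr[1L], "-", pr[2L]),
                 estimate = est, t = tval, df = df,
                 p = 2 * pt(-abs(tval), df))
    }))
  }
  out <- if (within == "overall") {
    one_group(rep(TRUE, length(y)), "overall")
  } else {
    do.call(rbind, lapply(sort(unique(detail$J)), function(jj)
      one_group(detail$J == jj, paste0("J=", jj))))
  }
  out$p <- stats::p.adjust(out$p, method = adjust)
  rownames(out) <- NULL
  out
}
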