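#' Per-item root mean square error across replicates
#'
#' @param estimates numeric vector of per-replicate point estimates (posterior
#'   means) for one item parameter.
#' @param truth the generating value.
#' @return \code{sqrt(mean((estimates - truth)^2))}.
#' @examples
#' item_rmse(c(1, 3), 2)  # 1
#' @export
item_rmse <- function(estimates, truth) {
  if (!length(estimates)) stop("'estimates' must be non-empty")
  sqrt(mean((estimates - truth)^2))
}

#' Per-item bias across replicates
#'
#' Mean signed estimation error; positive values indicate overestimation.
#'
#' @inheritParams item_rmse
#' @return \code{mean(estimates - truth)}.
#' @export
item_bias <- function(estimates, truth) {
  if (!length(estimates)) stop("'estimates' must be non-empty")
  mean(estimates - truth)
}

#' Summarize one design cell of per-item recovery records
#'
#' Aggregates item-level detail for a single (node, N, J) cell: the cell
#' RMSE and bias are means over items of the per-item values; the mean
#' estimate is the grand mean of the item-level mean posterior means; its SE
#' is the sd of the item-level means divided by sqrt(item count); the 95%
#' interval is mean +/- 1.96 SE.
#'
#' @param detail data.frame of per-item records for one cell with columns
#'   \code{rmse}, \code{bias}, \code{mean_est}.
#' @return One-row data.frame: \code{rmse}, \code{bias}, \code{mean_est},
#'   \code{se}, \code{ci_lo}, \code{ci_hi}, \code{items}.
#' @export
cell_summary <- function(detail) {
  need <- c("rmse", "bias", "mean_est")
  if (!all(need %in% names(detail)))
    stop("'detail' must have columns rmse, bias, mean_est")
  m <- nrow(detail)
  if (m < 2L) stop("cell summaries need at least 2 items (SE undefined)")
  mu <- mean(detail$mean_est)
  se <- sd(detail$mean_est) / sqrt(m)
  data.frame(rmse = mean(detail$rmse), bias = mean(detail$bias),
             mean_est = mu, se = se,
             ci_lo = mu - 1.96 * se, ci_hi = mu + 1.96 * se,
             items = m)
}

#' Build per-item recovery detail records
#'
#' Computes per-item RMSE, bias and mean estimate for both the
#' discrimination (alpha) and intercept (d) parameters, for every node, from
#' a replicates x node x item array of posterior means and the generating
#' truth. Scoring is on the intercept scale \code{d = alpha * b} by default;
#' \code{scale = "b"} scores difficulties on the trait scale instead.
#'
#' @param est_alpha,est_d arrays (replicates x 3 x J) of per-replicate
#'   posterior means.
#' @param truth an \code{\link{item_params}} object with the generating
#'   values.
#' @param N,J design-cell labels attached to the records.
#' @param scale score difficulties as intercepts \code{d} (default) or as
#'   \code{b}; supply \code{est_d} on the matching scale.
#' @return data.frame, one row per node x item: \code{node}, \code{N},
#'   \code{J}, \code{item}, \code{alpha_rmse}, \code{alpha_bias},
#'   \code{alpha_mean}, \code{d_rmse}, \code{d_bias}, \code{d_mean},
#'   \code{replicates}.
#' @export
recovery_detail <- function(est_alpha, est_d, truth, N, J, scale = c("d", "b")) {
  scale <- match.arg(scale)
  stopifnot(inherits(truth, "mpp_item_params"))
  da <- dim(est_alpha)
  if (length(da) != 3L || da[2L] != 3L || da[3L] != truth$J ||
      !identical(da, dim(est_d)))
    stop("estimate arrays must be replicates x 3 x J and match 'truth'")
  true_d <- if (scale == "d") truth$d else truth$b
  rows <- expand.grid(item = seq_len(truth$J), node = MPP_NODES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(r) {
    k <- match(rows$node[r], MPP_NODES); j <- rows$item[r]
    ea <- est_alpha[, k, j]; ed <- est_d[, k, j]
    data.frame(node = rows$node[r], N = N, J = J, item = j,
               alpha_rmse = item_rmse(ea, truth$alpha[k, j]),
               alpha_bias = item_bias(ea, truth$alpha[k, j]),
               alpha_mean = mean(ea),
               d_rmse = item_rmse(ed, true_d[k, j]),
               d_bias = item_bias(ed, true_d[k, j]),
               d_mean = mean(ed),
               replicates = da[1L])
  }))
  out$node <- factor(out$node, levels = MPP_NODES)
  rownames(out) <- NULL
  out
}

# Detail records when the generating parameters differ per replicate
# (item-parameter refresh mode): each replicate is scored against its own
# truth, so RMSE/bias are computed from the per-replicate errors directly.
detail_from_errors <- function(est_alpha, est_d, tru_alpha, tru_d, N, J) {
  Jn <- dim(est_alpha)[3L]
  rows <- expand.grid(item = seq_len(Jn), node = MPP_NODES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(r) {
    k <- match(rows$node[r], MPP_NODES); j <- rows$item[r]
    ea <- est_alpha[, k, j] - tru_alpha[, k, j]
    ed <- est_d[, k, j] - tru_d[, k, j]
    data.frame(node = rows$node[r], N = N, J = J, item = j,
               alpha_rmse = sqrt(mean(ea^2)), alpha_bias = mean(ea),
               alpha_mean = mean(est_alpha[, k, j]),
               d_rmse = sqrt(mean(ed^2)), d_bias = mean(ed),
               d_mean = mean(est_d[, k, j]),
               replicates = dim(est_alpha)[1L])
  }))
  out$node <- factor(out$node, levels = MPP_NODES)
  rownames(out) <- NULL
  out
}

#' Cell-level recovery table
#'
#' Aggregates per-item detail records into one row per (node, N, J) design
#' cell for both the alpha and d parameters, the package's analogue of a
#' printed recovery table: RMSE, bias, mean estimate, SE and 95% CI per
#' cell.
#'
#' @param detail data.frame from \code{\link{recovery_detail}} (rows from
#'   several cells may be concatenated).
#' @return data.frame keyed by \code{node}, \code{N}, \code{J} with columns
#'   \code{alpha_rmse}, \code{alpha_bias}, \code{alpha_mean},
#'   \code{alpha_se}, \code{alpha_ci_lo}, \code{alpha_ci_hi} and the same
#'   six for \code{d}, plus \code{items}.
#' @export
recovery_table <- function(detail) {
  key <- interaction(detail$node, detail$N, detail$J, drop = TRUE)
  out <- do.call(rbind, lapply(split(detail, key), function(cell) {
    a <- cell_summary(data.frame(rmse = cell$alpha_rmse,
                                 bias = cell$alpha_bias,
                                 mean_est = cell$alpha_mean))
    d <- cell_summary(data.frame(rmse = cell$d_rmse, bias = cell$d_bias,
                                 mean_est = cell$d_mean))
    data.frame(node = cell$node[1L], N = cell$N[1L], J = cell$J[1L],
               alpha_rmse = a$rmse, alpha_bias = a$bias,
               alpha_mean = a$mean_est, alpha_se = a$se,
               alpha_ci_lo = a$ci_lo, alpha_ci_hi = a$ci_hi,
               d_rmse = d$rmse, d_bias = d$bias, d_mean = d$mean_est,
               d_se = d$se, d_ci_lo = d$ci_lo, d_ci_hi = d$ci_hi,
               items = a$items)
  }))
  out <- out[order(out$node, out$J, out$N), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Node-level mean RMSEs
#'
#' Grand means of the per-item RMSE records per node, the study's headline
#' quantities (equal-weight mean over all item-level observations).
#'
#' @param detail data.frame from \code{\link{recovery_detail}}.
#' @return data.frame: \code{node}, \code{alpha_rmse}, \code{d_rmse}.
#' @export
node_means <- function(detail) {
  out <- do.call(rbind, lapply(split(detail, detail$node), function(g)
    data.frame(node = g$node[1L],
               alpha_rmse = mean(g$alpha_rmse),
               d_rmse = mean(g$d_rmse))))
  rownames(out) <- NULL
  out[order(out$node), , drop = FALSE]
}
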