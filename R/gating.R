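# Otsu threshold on a numeric vector (log intensities): exhaustive search over
# histogram cut points for the split maximizing between-class variance. Returns
# the threshold and the between-class variance fraction of total variance,
# used as a bimodality check: a clean two-mode split approaches 1, while the
# optimal split of a single Gaussian mode reaches only ~0.64.
otsu_split <- function(x, n_breaks = 256) {
  h <- graphics::hist(x, breaks = n_breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  mu_total <- sum(p * mids)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  between <- (mu_total * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  k <- which.max(between)
  total_var <- sum(p * (mids - mu_total)^2)
  list(threshold = h$breaks[k + 1],
       separation = if (total_var > 0) between[k] / total_var else 0)
}

# Local maxima of a density object, ordered by decreasing height.
density_modes <- function(d) {
  y <- d$y
  i <- which(diff(sign(diff(y))) == -2) + 1
  if (length(y) > 1) {
    if (y[1] > y[2]) i <- c(1, i)
    if (y[length(y)] > y[length(y) - 1]) i <- c(i, length(y))
  }
  i[order(-y[i])]
}

#' Gate cells into EdU-positive and EdU-negative
#'
#' Thresholds log10 EdU intensity. The `"valley"` method takes the density
#' minimum between the two largest modes of a kernel-density estimate
#' (Silverman bandwidth); when the distribution is effectively unimodal it
#' falls back to an Otsu split on the binned log intensities, and if even that
#' split fails a between-class-variance separation check the population is
#' declared all-negative (no EdU-positive mode present, as after a complete
#' licensing block). `"otsu"` forces the fallback path; `"fixed"` applies
#' `fixed_threshold` on the raw intensity scale.
#'
#' @param cells A `cell_table` with an `edu` column.
#' @param method `"valley"` (default), `"otsu"` or `"fixed"`.
#' @param fixed_threshold Raw-intensity threshold for `method = "fixed"`.
#' @param min_cells Minimum population size for the automatic methods
#'   (default 50).
#' @param valley_depth_max Accept a valley only if the density minimum is below
#'   this fraction of the smaller flanking mode (default 0.5).
#' @param otsu_separation_min Minimum between-class variance fraction for an
#'   Otsu split to count as bimodal (default 0.8).
#' @return A `gate_result` list: per-cell `edu_status` factor, the `threshold`
#'   used (raw scale; `Inf` when all-negative), `method_used`,
#'   `percent_edu_positive`.
#' @export
gate_edu_positive <- function(cells, method = c("valley", "otsu", "fixed"),
                              fixed_threshold = NULL, min_cells = 50,
                              valley_depth_max = 0.5,
                              otsu_separation_min = 0.8) {
  method <- match.arg(method)
  edu <- cells$edu
  if (any(edu < 0)) stop("EdU intensities must be non-negative", call. = FALSE)
  if (method == "fixed") {
    if (is.null(fixed_threshold)) {
      stop("fixed_threshold is required for method = 'fixed'", call. = FALSE)
    }
    thr <- fixed_threshold
    used <- "fixed"
  } else {
    if (length(edu) < min_cells) {
      stop("automatic gating needs >= ", min_cells,
           " cells; supply a fixed threshold instead", call. = FALSE)
    }
    lx <- log10(pmax(edu, .Machine$double.eps))
    thr <- NA_real_
    used <- method
    if (method == "valley") {
      d <- stats::density(lx, bw = "nrd0")
      modes <- density_modes(d)
      modes <- modes[d$y[modes] >= 0.05 * max(d$y)]  # drop KDE ripple
      if (length(modes) >= 2) {
        m2 <- sort(modes[1:2])
        between <- m2[1]:m2[2]
        valley <- between[which.min(d$y[between])]
        if (d$y[valley] <= valley_depth_max * min(d$y[m2])) {
          thr <- 10^d$x[valley]
        }
      }
      if (is.na(thr)) used <- "otsu"
    }
    if (used == "otsu") {
      sp <- otsu_split(lx)
      thr <- if (sp$separation >= otsu_separation_min) 10^sp$threshold else Inf
    }
  }
  status <- factor(ifelse(edu > thr, "positive", "negative"),
                   levels = c("negative", "positive"))
  structure(
    list(edu_status = status, threshold = thr, method_used = used,
         percent_edu_positive = 100 * mean(status == "positive")),
    class = "gate_result"
  )
}

#' Classify cells into cell-cycle phases
#'
#' Scale-free DAPI/EdU staging: the 2N DNA-content mode `m` is located as the
#' largest mode of the log10 DAPI density; cells are EdU-gated with
#' [gate_edu_positive()]; EdU-negative cells with DAPI in `[0.75 m, 1.5 m)` are
#' G1 and EdU-negative cells at or above `1.5 m` (the band around the 4N mode
#' `2 m`) are G2/M; every other cell — EdU-positive, or outside those DNA
#' bands — is S. Mid-S cells are flagged as the S-phase cells whose Cyclin A2
#' lies within the interquartile band of S-phase Cyclin A2 (a surrogate for
#' gating mid-S by intermediate Cyclin A2 levels). Because the gates are
#' defined relative to modes on log intensities, classification is invariant to
#' a common multiplicative rescaling of any channel.
#'
#' @param cells A `cell_table` with `dapi`, `edu` and optionally `cyclin_a2`.
#' @param min_cells Minimum population size (default 100).
#' @param gate_method EdU gating method, see [gate_edu_positive()].
#' @return A `gate_result` list: `phase` factor (`G1`, `S`, `G2M`), `mid_s`
#'   logical (all `FALSE` without `cyclin_a2`), `edu_status`, `dapi_2n_mode`,
#'   `threshold` (EdU), `percent_edu_positive`, `phase_counts`.
#' @export
classify_cell_cycle <- function(cells, min_cells = 100, gate_method = "valley") {
  dapi <- cells$dapi
  if (length(dapi) < min_cells) {
    stop("cell-cycle classification needs >= ", min_cells, " cells", call. = FALSE)
  }
  if (any(dapi <= 0)) stop("DAPI intensities must be positive", call. = FALSE)
  d <- stats::density(log10(dapi), bw = "nrd0")
  modes <- density_modes(d)
  if (length(modes) == 0) {
    stop("failed to locate a 2N DAPI mode; inspect the intensity histogram",
         call. = FALSE)
  }
  m <- 10^d$x[modes[1]]
  gate <- gate_edu_positive(cells, method = gate_method, min_cells = min(min_cells, 50))
  edu_pos <- gate$edu_status == "positive"
  phase <- rep("S", length(dapi))
  phase[!edu_pos & dapi >= 0.75 * m & dapi < 1.5 * m] <- "G1"
  phase[!edu_pos & dapi >= 1.5 * m] <- "G2M"
  phase <- factor(phase, levels = c("G1", "S", "G2M"))
  mid_s <- rep(FALSE, length(dapi))
  if ("cyclin_a2" %in% names(cells) && any(phase == "S")) {
    cyc_s <- cells$cyclin_a2[phase == "S"]
    q <- stats::quantile(cyc_s, c(0.25, 0.75), names = FALSE)
    mid_s <- phase == "S" & cells$cyclin_a2 >= q[1] & cells$cyclin_a2 <= q[2]
  }
  structure(
    list(phase = phase, mid_s = mid_s, edu_status = gate$edu_status,
         dapi_2n_mode = m, threshold = gate$threshold,
         percent_edu_positive = gate$percent_edu_positive,
         phase_counts = table(phase)),
    class = "gate_result"
  )
}

#' Summarize replicate percentages
#'
#' Sample mean, sample SD (n-1 denominator) and SEM of per-replicate values,
#' as drawn as mean ± error bars over technical replicates.
#'
#' @param values Numeric vector, one entry per replicate (n >= 2).
#' @return List with `n`, `mean`, `sd`, `sem`.
#' @export
summarize_replicates <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 replicates", call. = FALSE)
  s <- stats::sd(values)
  list(n = n, mean = mean(values), sd = s, sem = s / sqrt(n))
}

#' Paired two-tailed t-test
#'
#' The per-figure-legend test: on paired replicate values `a` and `b`, with
#' `d = a - b`, `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees of freedom
#' and a two-tailed p-value. Degenerate inputs follow the reporting convention
#' for replicate tables: identical vectors give `t = 0, p = 1`; zero-variance
#' differences with nonzero mean give `p = 0` with `zero_variance = TRUE`.
#'
#' @param a,b Equal-length numeric vectors of paired replicate values (n >= 2).
#' @return A `test_summary` list: `n_replicates`, `mean_a`, `mean_b`,
#'   `mean_difference`, `sd_difference`, `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `zero_variance`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("need at least 2 replicate pairs", call. = FALSE)
  d <- a - b
  sd_d <- stats::sd(d)
  zero_var <- sd_d == 0
  if (zero_var) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    t_stat <- mean(d) / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  structure(
    list(n_replicates = n, mean_a = mean(a), mean_b = mean(b),
         mean_difference = mean(d), sd_difference = sd_d,
         t_statistic = t_stat, degrees_of_freedom = n - 1L, p_value = p,
         zero_variance = zero_var),
    class = "test_summary"
  )
}

#' @export
print.test_summary <- function(x, ...) {
  cat(sprintf(
    "paired two-tailed t-test: n = %d, mean difference %.4g, t = %.4g (df %d), p = %.4g%s\n",
    x$n_replicates, x$mean_difference, x$t_statistic, x$degrees_of_freedom,
    x$p_value, if (x$zero_variance) " [zero-variance differences]" else ""))
  invisible(x)
}
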