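#' Define a G1 treatment schedule
#'
#' A treatment schedule describes when, during a G1 phase of given duration,
#' origin licensing is pharmacologically halted. Two kinds of window are
#' distinguished because they correspond to different drugs — degron-mediated
#' degradation of the MCM loaders CDC6/CDT1, and CDK4/6 inhibition (palbociclib
#' class) — but both simply stop the accumulation of licensed origins while they
#' are active: the two activities act in the same pathway, so blocked time is
#' the union of the windows.
#'
#' @param g1_duration G1 length in hours. Default 12 h, the span between mitotic
#'   release and S-phase entry in the synchronised cultures this model emulates.
#' @param licensing_block_windows List of `c(start, end)` hour pairs during which
#'   the licensing machinery is degraded.
#' @param cdk46_block_windows List of `c(start, end)` hour pairs of CDK4/6
#'   inhibition.
#' @param licensing_exponent Dimensionless exponent (>= 1) mapping the licensed
#'   fraction of G1 to downstream firing proficiency,
#'   `proficiency = licensed_fraction^licensing_exponent`. The default of 2
#'   encodes the observation that partial licensing windows suppress origin
#'   firing more than proportionally, without asserting a mechanism; the true
#'   dose-response between loaded MCM and firing is not quantified, so this is a
#'   placeholder knob.
#' @return A `treatment_schedule` object.
#' @examples
#' # licensing blocked for the first 4 h of a 12-h G1:
#' sch <- treatment_schedule(12, licensing_block_windows = list(c(0, 4)))
#' licensed_fraction(sch)  # 8/12
#' @export
treatment_schedule <- function(g1_duration = 12,
                               licensing_block_windows = list(),
                               cdk46_block_windows = list(),
                               licensing_exponent = 2) {
  if (!is.finite(g1_duration) || g1_duration <= 0) {
    stop("g1_duration must be positive", call. = FALSE)
  }
  if (!is.finite(licensing_exponent) || licensing_exponent < 1) {
    stop("licensing_exponent must be >= 1", call. = FALSE)
  }
  check_windows <- function(w, what) {
    if (length(w) == 0) return(list())
    w <- lapply(w, as.numeric)
    for (x in w) {
      if (length(x) != 2 || !all(is.finite(x))) {
        stop(what, " windows must be numeric [start, end] pairs", call. = FALSE)
      }
      if (x[1] >= x[2]) stop(what, " window start must precede end", call. = FALSE)
      if (x[1] < 0 || x[2] > g1_duration) {
        stop(what, " windows must lie within [0, g1_duration]", call. = FALSE)
      }
    }
    w <- w[order(vapply(w, `[`, numeric(1), 1))]
    if (length(w) > 1) {
      starts <- vapply(w, `[`, numeric(1), 1)
      ends <- vapply(w, `[`, numeric(1), 2)
      if (any(starts[-1] < ends[-length(ends)])) {
        stop(what, " windows of the same kind must not overlap", call. = FALSE)
      }
    }
    w
  }
  structure(
    list(
      g1_duration = g1_duration,
      licensing_block_windows = check_windows(licensing_block_windows, "licensing_block"),
      cdk46_block_windows = check_windows(cdk46_block_windows, "cdk46_block"),
      licensing_exponent = licensing_exponent
    ),
    class = "treatment_schedule"
  )
}

#' @export
print.treatment_schedule <- function(x, ...) {
  fmt <- function(w) {
    if (length(w) == 0) return("none")
    paste(vapply(w, function(p) sprintf("[%g,%g]", p[1], p[2]), ""), collapse = " ")
  }
  cat(sprintf(
    "treatment_schedule: G1 %g h; licensing blocks %s; CDK4/6 blocks %s; exponent %g\n",
    x$g1_duration, fmt(x$licensing_block_windows), fmt(x$cdk46_block_windows),
    x$licensing_exponent))
  cat(sprintf("  licensed fraction %.4f -> firing proficiency %.4f\n",
              licensed_fraction(x), firing_proficiency(x)))
  invisible(x)
}

# Total measure of the union of an interval list (intervals validated upstream).
union_measure <- function(windows) {
  if (length(windows) == 0) return(0)
  m <- do.call(rbind, windows)
  m <- m[order(m[, 1]), , drop = FALSE]
  total <- 0
  cur <- m[1, ]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= cur[2]) {
      cur[2] <- max(cur[2], m[i, 2])
    } else {
      total <- total + (cur[2] - cur[1])
      cur <- m[i, ]
    }
  }
  total + (cur[2] - cur[1])
}

#' Fraction of G1 during which licensing could accumulate
#'
#' Licensing proceeds cumulatively through G1 and is halted whenever either a
#' licensing-block (CDC6/CDT1 degradation) or a CDK4/6-inhibition window is
#' active; already-loaded helicases are retained. The licensed fraction is the
#' unblocked share of G1: `(g1_duration - |union of all windows|) / g1_duration`.
#'
#' @param schedule A [treatment_schedule()].
#' @return Fraction in `[0, 1]`.
#' @export
licensed_fraction <- function(schedule) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  blocked <- union_measure(c(schedule$licensing_block_windows,
                             schedule$cdk46_block_windows))
  max(0, min(1, (schedule$g1_duration - blocked) / schedule$g1_duration))
}

#' Origin-firing proficiency implied by a schedule
#'
#' `licensed_fraction(schedule) ^ licensing_exponent`: the multiplicative factor
#' applied to every origin's firing efficiency downstream.
#'
#' @param schedule A [treatment_schedule()].
#' @return Proficiency in `[0, 1]`.
#' @export
firing_proficiency <- function(schedule) {
  licensed_fraction(schedule)^schedule$licensing_exponent
}
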