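## Polarization time-trace decomposition. Each detected PSF yields a trace
## of on-events with a polarization value p = ch1/(ch1+ch2) per event; a
## frozen dipole makes p piecewise-constant across blinking returns of the
## same fluorophore. Decomposition runs in two stages:
##   1. divisive top-down change-point segmentation of the 1D p-signal,
##      accepted by a BIC gain scaled by `alpha`;
##   2. a joint mixture refit over (p, x, y) -- polarization and position
##      simultaneously -- which sets the final state count and assignments.

#' Build a polarization trace from an event table
#'
#' Keeps on-events only (off-times omitted), sorted by frame, dropping
#' zero-photon events; `p = counts_ch1 / (counts_ch1 + counts_ch2)`.
#'
#' @param events Event table rows for one particle (see [emit_events()]).
#' @return A `polarization_trace`: data.frame with `frame`, `x_nm`, `y_nm`,
#'   `p`, `photons` (plus `fluorophore_index` when present, for validation
#'   against ground truth).
#' @export
polarization_trace <- function(events) {
  tot <- events$counts_ch1 + events$counts_ch2
  keep <- tot > 0
  ev <- events[keep, , drop = FALSE]
  out <- data.frame(frame = ev$frame, x_nm = ev$x_nm, y_nm = ev$y_nm,
                    p = ev$counts_ch1 / tot[keep], photons = tot[keep])
  if (!is.null(ev$fluorophore_index))
    out$fluorophore_index <- ev$fluorophore_index
  out <- out[order(out$frame), , drop = FALSE]
  class(out) <- c("polarization_trace", "data.frame")
  out
}

## Stage 1: recursive binary splitting of the p sequence. A split of a
## segment is kept when the Gaussian-likelihood BIC improves, with the
## penalty scaled by alpha (alpha = 1 is plain BIC). Returns change-point
## boundaries (start indices of segments).
.divisive_segments <- function(p, alpha = 1, min_len = 3) {
  n <- length(p)
  segments <- list(c(1L, n))
  out <- list()
  sse <- function(x) sum((x - mean(x))^2)
  while (length(segments)) {
    seg <- segments[[1]]; segments <- segments[-1]
    a <- seg[1]; b <- seg[2]; len <- b - a + 1
    if (len < 2 * min_len) { out[[length(out) + 1]] <- seg; next }
    x <- p[a:b]
    s0 <- sse(x)
    ## best split point by minimum pooled SSE
    cuts <- min_len:(len - min_len)
    css <- cumsum(x); css2 <- cumsum(x^2)
    nl <- cuts; nr <- len - cuts
    sl <- css2[cuts] - css[cuts]^2 / nl
    sr <- (css2[len] - css2[cuts]) - (css[len] - css[cuts])^2 / nr
    tot <- sl + sr
    k <- which.min(tot)
    ## BIC gain: 2 extra params (mean + change point) per split
    gain <- len * log((s0 + 1e-12) / (tot[k] + 1e-12))
    if (gain > alpha * 2 * log(len)) {
      cut <- a + cuts[k] - 1L
      segments <- c(segments, list(c(a, cut)), list(c(cut + 1L, b)))
    } else {
      out[[length(out) + 1]] <- seg
    }
  }
  out <- out[order(vapply(out, `[`, integer(1), 1))]
  do.call(rbind, out)
}

## Primary segmentation of a trace into single-dipole runs. Blinking means
## events arrive in on-bursts separated by omitted off-times, so a frame gap
## (diff > 1) starts a new burst; two events in the same frame (diff == 0)
## are simultaneous emitters and must also be separated; and a polarization
## jump large relative to the binomial shot noise of the two events marks a
## switch within a run of consecutive frames. Within the resulting runs,
## divisive change-point splitting (BIC, scaled by alpha) catches anything
## the jump rule missed.
.trace_segments <- function(trace, alpha = 1) {
  n <- nrow(trace)
  if (n == 1) return(matrix(c(1L, 1L), 1))
  p <- trace$p; N <- pmax(trace$photons, 1)
  i <- seq_len(n - 1)
  pbar <- (p[i] * N[i] + p[i + 1] * N[i + 1]) / (N[i] + N[i + 1])
  sd_jump <- sqrt(pmax(pbar * (1 - pbar), 1e-4) * (1 / N[i] + 1 / N[i + 1]))
  ## events sharing a frame are simultaneous emitters; isolate them (and
  ## their neighbors) into singleton segments so no segment mixes dipoles
  dup <- trace$frame %in% trace$frame[duplicated(trace$frame)]
  bnd <- which(diff(trace$frame) != 1 | abs(diff(p)) > 4 * sd_jump |
                 dup[-n] | dup[-1])
  starts <- c(1L, bnd + 1L); ends <- c(bnd, n)
  segs <- cbind(starts, ends)
  ## refine long runs by change-point splitting
  out <- lapply(seq_len(nrow(segs)), function(r) {
    a <- segs[r, 1]; b <- segs[r, 2]
    if (b - a + 1 < 6) return(matrix(c(a, b), 1))
    sub <- .divisive_segments(p[a:b], alpha = alpha)
    sub + a - 1L
  })
  do.call(rbind, out)
}

## Segment-level state-count selection. Each stage-1 segment contributes its
## mean feature vector (p, x, y in noise-standardized units) observed with
## known isotropic noise 1/sqrt(n_s); a k-cluster classification likelihood
## with weighted center updates is scored by BIC over candidate k. Working
## on segment means exploits the piecewise-constant temporal structure:
## state separations that are marginal event-by-event are decisive here.
.segment_state_count <- function(X, segs, max_states) {
  n_seg <- nrow(segs)
  m <- t(apply(segs, 1, function(r) colMeans(X[r[1]:r[2], , drop = FALSE])))
  ns <- segs[, 2] - segs[, 1] + 1
  kmax <- min(max_states, n_seg)
  d <- ncol(X)
  score <- rep(NA_real_, kmax)
  labels <- vector("list", kmax)
  for (k in seq_len(kmax)) {
    if (k == 1) {
      ctr <- matrix(colSums(m * ns) / sum(ns), 1)
      lab <- rep(1L, n_seg)
    } else {
      km <- tryCatch(
        suppressWarnings(stats::kmeans(m, centers = k, nstart = 10)),
        error = function(e) NULL)
      if (is.null(km)) next
      lab <- km$cluster
      for (it in 1:10) {  # Lloyd iterations with n_s-weighted centers
        ctr <- t(vapply(seq_len(k), function(c) {
          w <- ns[lab == c]
          if (!length(w)) return(rep(Inf, d))
          colSums(m[lab == c, , drop = FALSE] * w) / sum(w)
        }, numeric(d)))
        d2 <- vapply(seq_len(k), function(c)
          rowSums(sweep(m, 2, ctr[c, ])^2), numeric(n_seg))
        new_lab <- max.col(-d2)
        if (all(new_lab == lab)) break
        lab <- new_lab
      }
      if (length(unique(lab)) < k) next
    }
    ## loglik of segment means: event noise is isotropic with relative
    ## precision n_s per segment; its scale sigma^2 is estimated per k from
    ## the clustering residuals (ML), so miscalibrated standardization or
    ## residually impure segments cannot masquerade as extra states
    resid2 <- rowSums((m - ctr[lab, , drop = FALSE])^2)
    sigma2 <- max(mean(resid2 * ns / d), 1e-6)
    ll <- sum(vapply(seq_len(n_seg), function(s) {
      mu <- ctr[lab[s], ]
      w <- sum(lab == lab[s]) / n_seg
      sum(stats::dnorm(m[s, ], mu, sqrt(sigma2 / ns[s]), log = TRUE)) + log(w)
    }, 0))
    score[k] <- -2 * ll + (d * k + k) * log(n_seg)
    labels[[k]] <- lab
  }
  k_best <- which.min(score)
  list(k = k_best, score = score,
       event_labels = labels[[k_best]][rep(seq_len(n_seg), ns)])
}

#' Decompose a polarization trace into dipole states
#'
#' Stage 1 segments the 1D polarization signal by divisive change-point
#' splitting with a BIC acceptance rule (penalty scaled by `alpha`). Stage 2
#' refits the event-to-state assignment with a Gaussian mixture over
#' `(p, x, y)` jointly (coordinates standardized to the trace's positional
#' SD), choosing the number of states in `1..max_states` by BIC. Two
#' fluorophores with identical dipole azimuths but distinct positions are
#' therefore still separated.
#'
#' @param trace A `polarization_trace` (or an event table, which is
#'   converted).
#' @param max_states Largest candidate state count (reduced automatically
#'   when the trace is short).
#' @param alpha Multiplier on the BIC change-point penalty (1 = plain BIC).
#' @return A `state_decomposition`: list with `n_states`, `assignment`
#'   (integer per event, states ordered by ascending mean p), `state_means`
#'   (mean p per state), `criterion` (per-k BIC scores of the stage-2
#'   mixture), `snr` (see [trace_snr()]) and the `trace` itself.
#' @export
decompose_trace <- function(trace, max_states = 4, alpha = 1) {
  if (!inherits(trace, "polarization_trace")) trace <- polarization_trace(trace)
  n <- nrow(trace)
  if (n == 0) stop("empty trace")
  stopifnot(max_states >= 1)
  max_states <- min(max_states, n)
  p <- trace$p

  ## stage 1: change-point segmentation into single-dipole runs. A frozen
  ## dipole makes p piecewise constant over blink bursts, so pooled
  ## within-segment SDs estimate the per-event measurement noise of each
  ## coordinate free of between-state separation -- exactly the scale the
  ## stage-2 standardization needs.
  segs <- .trace_segments(trace, alpha = alpha)
  within_sd <- function(x) {
    ss <- 0; df <- 0
    for (r in seq_len(nrow(segs))) {
      xs <- x[segs[r, 1]:segs[r, 2]]
      if (length(xs) >= 2) { ss <- ss + sum((xs - mean(xs))^2); df <- df + length(xs) - 1 }
    }
    if (df > 0) sqrt(ss / df) else stats::sd(x)
  }

  ## stage 2: state-count selection on noise-standardized (p, x, y) at the
  ## segment level (see .segment_state_count), then a joint mixture refit of
  ## the event-to-state assignment at the selected count. The polarization
  ## enters through the arcsine variance-stabilizing transform
  ## z = asin(sqrt(p)), whose binomial shot noise SD is 1/(2 sqrt(photons))
  ## independent of p, so a single scale standardizes every state.
  z <- asin(sqrt(pmin(pmax(p, 0), 1)))
  sz <- mean(1 / (2 * sqrt(pmax(trace$photons, 1))))
  s_pos <- max(sqrt(within_sd(trace$x_nm) * within_sd(trace$y_nm)), 1e-6)
  X <- cbind(p = z / sz, x = trace$x_nm / s_pos, y = trace$y_nm / s_pos)

  sel <- .segment_state_count(X, segs, max_states)
  k <- sel$k
  classification <- sel$event_labels
  if (k > 1) {
    fit <- tryCatch(
      suppressWarnings(Mclust(X, G = k,
                              modelNames = c("EII", "VII", "VVI"),
                              verbose = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit) && length(unique(fit$classification)) == k)
      classification <- fit$classification
  }

  means_p <- vapply(seq_len(k), function(g)
    mean(p[classification == g]), 0)

  ## order states by ascending mean polarization
  ord <- order(means_p)
  relabel <- match(seq_along(ord), ord)
  assignment <- relabel[classification]

  dec <- structure(list(
    n_states = k,
    assignment = assignment,
    state_means = means_p[ord],
    criterion = stats::setNames(sel$score,
                                paste0("k", seq_along(sel$score))),
    n_segments_stage1 = nrow(segs),
    trace = trace
  ), class = "state_decomposition")
  dec$snr <- trace_snr(dec)
  dec
}

#' @export
print.state_decomposition <- function(x, ...) {
  cat(sprintf("<state_decomposition> %d state(s), %d events, SNR %.2f\n",
              x$n_states, nrow(x$trace), x$snr))
  cat("  mean p per state:", paste(sprintf("%.3f", x$state_means),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Polarization-trace signal-to-noise ratio
#'
#' Defined as the spread of the state means (max minus min mean
#' polarization) divided by the mean within-state SD of p. Single-state
#' traces have SNR 0.
#'
#' @param dec A `state_decomposition`.
#' @return Dimensionless SNR.
#' @export
trace_snr <- function(dec) {
  stopifnot(inherits(dec, "state_decomposition"))
  if (dec$n_states < 2) return(0)
  p <- dec$trace$p
  within <- vapply(seq_len(dec$n_states), function(s) {
    x <- p[dec$assignment == s]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x)
  }, 0)
  within <- mean(within, na.rm = TRUE)
  if (!is.finite(within) || within == 0) return(Inf)
  (max(dec$state_means) - min(dec$state_means)) / within
}

#' Select particles with exactly three dipole states
#'
#' Keeps particles whose trace decomposes into exactly 3 states with SNR
#' above `min_snr`; this is the trimer-selection step of the pipeline.
#'
#' @param decompositions List of `state_decomposition` objects.
#' @param min_snr SNR floor.
#' @return Logical vector marking the retained particles.
#' @export
select_three_state <- function(decompositions, min_snr = 3.5) {
  vapply(decompositions, function(d) {
    d$n_states == 3 && d$snr > min_snr
  }, logical(1))
}
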