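# Preferential-attachment model of multi-search retrieval. Each search
# returns m molecules; a pick duplicates an already-retrieved molecule with
# probability gamma (proportionally to its current retrieval count) and draws
# a never-retrieved molecule otherwise. The steady-state fraction of
# retrieval instances held by molecules retrieved exactly s times follows the
# closed-form recurrence below, whose tail is a power law with asymptotic
# exponent -(1 + 1/gamma).

.check_gamma <- function(gamma) {
  if (!is.numeric(gamma) || anyNA(gamma) || any(gamma <= 0) || any(gamma > 1)) {
    abort("`gamma` must lie in (0, 1].")
  }
  gamma
}

#' Steady-state overlap fractions of the preferential-attachment model
#'
#' Closed-form steady state of the retrieval growth equations, before any
#' large-`s` approximation: `O_1 = (1 - gamma) / (1 + gamma)` and
#' `O_s = gamma * (s - 1) * O_{s-1} / (1 + gamma * s)` for `s >= 2`. `O_s` is
#' the fraction of all retrieval instances (`m * t` after `t` searches) held
#' by molecules retrieved exactly `s` times; under the steady-state growth
#' `X_s(t) = O_s * m * t` the fractions satisfy `sum(s * O_s) = 1` in the
#' infinite-`s` limit.
#'
#' At `gamma = 1` every `O_s` is 0: all picks are preferential and no steady
#' inflow of new molecules exists.
#'
#' @param gamma Preferential-retrieval weight in `(0, 1]`.
#' @param n Number of searches (profile length).
#' @return A `"steady_state_overlap"` tibble: `s` (1..n), `O`.
#' @examples
#' steady_state_overlap(0.9, 25)
#' @export
steady_state_overlap <- function(gamma, n = 25L) {
  .check_gamma(gamma)
  if (n < 2L) abort("`n` must be >= 2.")
  O <- numeric(n)
  O[1L] <- (1 - gamma) / (1 + gamma)
  for (s in 2:n) O[s] <- gamma * (s - 1) * O[s - 1L] / (1 + gamma * s)
  structure(
    tibble::tibble(s = seq_len(n), O = O),
    class = c("steady_state_overlap", class(tibble::tibble())),
    gamma = gamma
  )
}

#' Asymptotic power-law exponent of the model
#'
#' In the large-`s` limit the steady-state recurrence gives
#' `O_s ~ a * s^b` with `b = -(1 + 1/gamma)`. The exponent is bounded above
#' by -2, attained at `gamma = 1` (the classical Lotka slope); shallower
#' observed slopes arise only at finite `s` (see [effective_slope()]).
#'
#' @param gamma Preferential-retrieval weight(s) in `(0, 1]`; vectorized.
#' @return `-(1 + 1/gamma)`.
#' @export
asymptotic_exponent <- function(gamma) {
  .check_gamma(gamma)
  -(1 + 1 / gamma)
}

#' Effective log-log slope of the steady-state overlap at finite n
#'
#' Composes [steady_state_overlap()] with [loglog_fit()]: the ordinary
#' least-squares slope of `log10(O_s)` against `log10(s)` over a finite fit
#' range. Because the recurrence only reaches its power-law tail
#' asymptotically, the effective slope at small `n` is shallower than
#' `asymptotic_exponent(gamma)` and approaches it from above as `n` grows.
#'
#' @inheritParams steady_state_overlap
#' @param s_range Fit range, default `1..n` (the full profile, matching
#'   empirical overlap plots that start at `s = 1`).
#' @return The fitted slope (a negative number).
#' @examples
#' effective_slope(0.9, 25) # about -1.923
#' @export
effective_slope <- function(gamma, n = 25L, s_range = seq_len(n)) {
  fit <- loglog_fit(steady_state_overlap(gamma, n), s_range = s_range)
  unname(fit$coefficients[["slope"]])
}

#' Probability that the next search hits the s-times-retrieved set
#'
#' Given the current tallies `X_s`, a single preferential pick lands on some
#' molecule currently retrieved exactly `s` times with probability
#' `gamma * s * X_s / (m * t)`, where `m * t = sum(s * X_s)` is the total
#' number of retrieval instances so far.
#'
#' @param state Data frame with columns `s` and `X` (counts of molecules
#'   retrieved exactly `s` times), or a numeric vector `X_s` indexed by `s`.
#' @param s Target retrieval count.
#' @param gamma Preferential-retrieval weight.
#' @return The selection probability; 0 when no molecule has count `s`.
#' @export
selection_probability <- function(state, s, gamma) {
  .check_gamma(gamma)
  if (is.data.frame(state)) {
    X <- state$X; ss <- state$s
  } else {
    X <- as.numeric(state); ss <- seq_along(X)
  }
  total <- sum(ss * X)
  if (total <= 0) abort("State holds no retrieval instances.")
  i <- match(s, ss)
  if (is.na(i) || X[i] == 0) return(0)
  gamma * s * X[i] / total
}

#' Simulate the preferential-attachment retrieval process
#'
#' Search 1 draws `m` distinct molecules uniformly from the database. Each
#' later search draws `m` distinct molecules one at a time: with probability
#' `gamma` the pick duplicates an already-retrieved molecule chosen
#' proportionally to its current retrieval count; otherwise it draws
#' uniformly among never-retrieved molecules. Picks already in the current
#' search's set are rejected and redrawn (a search output is a set).
#'
#' @param gamma Preferential-retrieval weight in `(0, 1]`, or 0 for the
#'   no-reinforcement limit in which every search draws fresh molecules.
#' @param n Number of searches.
#' @param m Molecules returned per search.
#' @param M Database size; must be at least `n * m` so draws never exhaust.
#' @param seed Optional seed for reproducibility.
#' @param record_trajectory Keep the full per-step tallies? The trajectory
#'   needs `n^2` cells, so disable it for long draw-level runs (large `n`,
#'   small `m`) where only the final counts matter.
#' @return A list of class `"pa_simulation"`: `trajectory` (tibble `t`, `s`,
#'   `X` after each step; `NULL` when not recorded), `counts` (a
#'   `"retrieval_counts"` over molecules `1..M`), and the parameters.
#' @export
simulate_pa_process <- function(gamma, n, m, M, seed = NULL,
                                record_trajectory = n <= 1000L) {
  if (gamma < 0 || gamma > 1) abort("`gamma` must lie in [0, 1].")
  if (M < n * m) abort("`M` must be at least `n * m` so draws cannot exhaust.")
  if (!is.null(seed)) set.seed(seed)
  count <- integer(M)
  instances <- integer(n * m)  # one entry per retrieval instance
  n_inst <- 0L
  unret <- seq_len(M); n_unret <- M; pos <- seq_len(M)
  traj <- if (record_trajectory) matrix(0L, nrow = n, ncol = n)  # row t: X_s
  for (t in seq_len(n)) {
    picked <- integer(m); k <- 0L
    in_cur <- logical(M)
    while (k < m) {
      if (t == 1L || gamma == 0 || runif(1) >= gamma) {
        j <- sample.int(n_unret, 1L); id <- unret[j]
        if (in_cur[id]) next
      } else {
        id <- instances[sample.int(n_inst, 1L)]
        if (in_cur[id]) next
      }
      k <- k + 1L; picked[k] <- id; in_cur[id] <- TRUE
    }
    for (id in picked) {
      if (count[id] == 0L) {
        j <- pos[id]; last <- unret[n_unret]
        unret[j] <- last; pos[last] <- j
        n_unret <- n_unret - 1L
      }
      count[id] <- count[id] + 1L
      n_inst <- n_inst + 1L; instances[n_inst] <- id
    }
    if (record_trajectory) traj[t, ] <- tabulate(count[count > 0L], nbins = n)
  }
  trajectory <- if (record_trajectory) {
    tibble::tibble(
      t = rep(seq_len(n), each = n), s = rep(seq_len(n), times = n),
      X = as.integer(t(traj))
    )
  }
  structure(
    list(
      trajectory = trajectory,
      counts = new_retrieval_counts(seq_len(M), count, n, m),
      gamma = gamma, n = n, m = m, M = M
    ),
    class = "pa_simulation"
  )
}

#' Estimate the preferential-retrieval weight from an overlap profile
#'
#' Two routes. `"recurrence_ls"` (default) fits the shape of the observed
#' `log O_s` to the steady-state recurrence with a free scale, minimizing the
#' mean squared log residual over `gamma` in `(0, 1)`; it is scale-invariant,
#' so counts, molecule fractions or instance fractions all work.
#' `"asymptotic_inversion"` inverts the asymptotic exponent from a log-log
#' slope, `gamma = -1 / (b + 1)`; it is only valid for `b < -2`, and slopes
#' at or above -2 are flagged as outside the model.
#'
#' Both routes assume the profile comes from the steady-state regime of the
#' process (many searches relative to the per-search batch); profiles from
#' short batched runs are dominated by the transient and bias the estimate
#' upward.
#'
#' @param profile An `"overlap_profile"`, `"steady_state_overlap"`, or a
#'   numeric vector of `O_s` values indexed by `s`; at least 3 positive
#'   buckets are required.
#' @param method `"recurrence_ls"` or `"asymptotic_inversion"`.
#' @param s_range Optional fit range.
#' @return A list of class `"gamma_estimate"`: `gamma` (`NA` when flagged),
#'   `method`, `out_of_model`, and for the inversion route the fitted
#'   `slope`.
#' @export
estimate_gamma <- function(profile, method = c("recurrence_ls", "asymptotic_inversion"),
                           s_range = NULL) {
  method <- match.arg(method)
  v <- .fit_values(profile, s_range)
  keep <- is.finite(v$y) & v$y > 0
  s <- v$s[keep]; y <- v$y[keep]
  if (length(y) < 3L) abort("Need >= 3 positive overlap buckets to estimate gamma.")
  if (method == "asymptotic_inversion") {
    fit <- loglog_fit(profile, s_range)
    b <- unname(fit$coefficients[["slope"]])
    out_of_model <- b >= -2
    if (out_of_model) {
      warn(sprintf(
        "Fitted slope %.3f is >= -2 and outside the model's asymptotic range; gamma is undefined.",
        b
      ))
    }
    est <- structure(
      list(gamma = if (out_of_model) NA_real_ else -1 / (b + 1),
           method = method, slope = b, out_of_model = out_of_model),
      class = "gamma_estimate"
    )
    return(est)
  }
  ly <- log(y)
  objective <- function(g) {
    p <- log(steady_state_overlap(g, max(s))$O[s])
    r <- ly - p
    mean((r - mean(r))^2)
  }
  opt <- optimize(objective, c(1e-3, 1 - 1e-9))
  structure(
    list(gamma = opt$minimum, method = method, out_of_model = FALSE),
    class = "gamma_estimate"
  )
}

#' @export
print.gamma_estimate <- function(x, ...) {
  if (x$out_of_model) {
    cat(sprintf("<gamma estimate> out of model (slope %.3f >= -2)\n", x$slope))
  } else {
    cat(sprintf("<gamma estimate> gamma = %.4f (%s)\n", x$gamma, x$method))
  }
  invisible(x)
}

#' Tidy a preferential-attachment simulation
#'
#' @param x A `"pa_simulation"`.
#' @param ... Unused.
#' @return The final-step overlap counts as a tibble `s`, `X`.
#' @method tidy pa_simulation
#' @export
tidy.pa_simulation <- function(x, ...) {
  dplyr::filter(x$trajectory, .data$t == x$n)[, c("s", "X")]
}

#' Glance at a preferential-attachment simulation
#'
#' @param x A `"pa_simulation"`.
#' @param ... Unused.
#' @return One-row tibble with the parameters, the number of distinct
#'   molecules retrieved, and the maximum retrieval count.
#' @method glance pa_simulation
#' @export
glance.pa_simulation <- function(x, ...) {
  tibble::tibble(
    gamma = x$gamma, n = x$n, m = x$m, M = x$M,
    n_distinct_retrieved = sum(x$counts$count > 0L),
    max_count = max(x$counts$count)
  )
}
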