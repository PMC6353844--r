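# Continuous-time Markov-chain dynamics of asynchronous Boolean networks:
# ensemble simulation (Gillespie, compiled engine), an R-level single
# trajectory, and an exact master-equation oracle for small models.

#' Enabled transitions of a network state
#'
#' Under asynchronous updating, a node is flippable exactly when its rule
#' value differs from its current value; the transition carries the node's
#' directional rate (`k_up` for 0 to 1, `k_down` for 1 to 0). Zero-rate
#' transitions are excluded, which is how strictly fixed nodes stay frozen.
#'
#' @param model a `logical_model`.
#' @param settings a `simulation_settings`.
#' @param state named 0/1 vector over all nodes.
#' @return tibble with columns `node`, `direction` ("up"/"down"), `rate`.
#' @export
enabled_transitions <- function(model, settings, state) {
  if (!setequal(names(state), model$nodes))
    stop("state must assign exactly the model's nodes", call. = FALSE)
  res <- purrr::map_dfr(model$nodes, function(nm) {
    cur <- as.integer(state[[nm]])
    target <- evaluate_rule(model$rules[[nm]], state)
    if (cur == target) return(NULL)
    i <- match(nm, settings$nodes$node)
    rate <- if (cur == 0L) settings$nodes$k_up[i] else settings$nodes$k_down[i]
    if (rate <= 0) return(NULL)
    tibble::tibble(node = nm, direction = if (cur == 0L) "up" else "down",
                   rate = rate)
  })
  if (nrow(res) == 0L)
    res <- tibble::tibble(node = character(0), direction = character(0),
                          rate = numeric(0))
  res
}

#' Simulate a single stochastic trajectory
#'
#' Reference R implementation of the Gillespie step: waiting times are
#' exponential with the total enabled rate and the flipped node is chosen
#' proportionally to its rate. The initial state is sampled node-wise from
#' the initial-state probabilities. Uses R's RNG (`set.seed()` applies);
#' the compiled ensemble engine uses its own per-trajectory streams.
#'
#' @inheritParams enabled_transitions
#' @param init optional named 0/1 vector to start from instead of sampling.
#' @return a `boolean_trajectory`: jump times, visited states, absorption flag.
#' @export
simulate_trajectory <- function(model, settings, init = NULL) {
  validate_model(model, settings)
  nodes <- model$nodes
  if (is.null(init)) {
    p <- settings$nodes$istate[match(nodes, settings$nodes$node)]
    state <- stats::setNames(as.integer(stats::runif(length(nodes)) < p), nodes)
  } else {
    state <- stats::setNames(as.integer(init[nodes]), nodes)
  }
  times <- 0
  states <- matrix(state, nrow = 1, dimnames = list(NULL, nodes))
  t <- 0
  absorbed <- FALSE
  repeat {
    tr <- enabled_transitions(model, settings, state)
    if (nrow(tr) == 0L) {
      absorbed <- TRUE
      break
    }
    total <- sum(tr$rate)
    t <- t + stats::rexp(1, rate = total)
    if (t >= settings$max_time) break
    pick <- tr$node[sample.int(nrow(tr), 1L, prob = tr$rate)]
    state[pick] <- 1L - state[pick]
    times <- c(times, t)
    states <- rbind(states, state)
  }
  structure(list(times = times, states = states, absorbed = absorbed,
                 max_time = settings$max_time),
            class = "boolean_trajectory")
}

#' @export
print.boolean_trajectory <- function(x, ...) {
  cat(sprintf("<boolean_trajectory> %d jumps over [0, %g]%s\n",
              length(x$times) - 1L, x$max_time,
              if (x$absorbed) ", absorbed" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.boolean_trajectory <- function(x, ...) {
  tibble::as_tibble(x$states) %>%
    dplyr::mutate(time = x$times, .before = 1)
}

#' Simulate an ensemble of stochastic trajectories
#'
#' Runs `settings$n_trajectories` independent Gillespie trajectories in the
#' compiled engine and aggregates them into time-binned node-activation and
#' model-state probability estimates. A trajectory contributes its
#' time-weighted occupancy to each bin, which is unbiased for jump
#' processes. Per-trajectory RNG streams are derived from the master seed
#' and the trajectory index, so results are reproducible and independent of
#' execution order.
#'
#' @inheritParams enabled_transitions
#' @param record_states record sparse per-bin model-state probabilities
#'   (default: only for models with at most 16 nodes).
#' @return an `ensemble_result`.
#' @examples
#' tm <- toy_model()
#' res <- simulate_ensemble(tm$model, tm$settings)
#' asymptotic_probabilities(res)
#' @export
simulate_ensemble <- function(model, settings, record_states = NULL) {
  validate_model(model, settings)
  n <- length(model$nodes)
  if (is.null(record_states)) record_states <- n <= 16L
  codes <- compile_rules(model)
  ord <- match(model$nodes, settings$nodes$node)
  raw <- .simulate_ensemble_cpp(
    codes,
    settings$nodes$k_up[ord], settings$nodes$k_down[ord],
    settings$nodes$istate[ord],
    settings$n_trajectories, settings$max_time, settings$time_bins,
    settings$seed, record_states
  )
  breaks <- seq(0, settings$max_time, length.out = settings$time_bins + 1L)
  colnames(raw$prob) <- model$nodes
  colnames(raw$se) <- model$nodes
  states <- NULL
  if (record_states) {
    states <- tibble::tibble(
      bin = raw$state_bin,
      state_key = raw$state_key,
      probability = raw$state_prob
    )
  }
  structure(
    list(node_prob = raw$prob, node_se = raw$se, states = states,
         breaks = breaks, times = (breaks[-1] + breaks[-length(breaks)]) / 2,
         nodes = model$nodes, outputs = model$outputs,
         n_trajectories = settings$n_trajectories,
         max_time = settings$max_time,
         asymptotic_window = settings$asymptotic_window,
         seed = settings$seed),
    class = "ensemble_result"
  )
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %d trajectories | %d nodes | %d bins over [0, %g]\n",
              x$n_trajectories, length(x$nodes), length(x$times), x$max_time))
  ap <- asymptotic_probabilities(x)
  cat("asymptotic node probabilities:\n")
  print(ap, n = 15)
  invisible(x)
}

#' @export
tidy.ensemble_result <- function(x, ...) {
  tibble::as_tibble(x$node_prob) %>%
    dplyr::mutate(time = x$times, .before = 1) %>%
    tidyr::pivot_longer(-"time", names_to = "node", values_to = "probability") %>%
    dplyr::left_join(
      tibble::as_tibble(x$node_se) %>%
        dplyr::mutate(time = x$times, .before = 1) %>%
        tidyr::pivot_longer(-"time", names_to = "node", values_to = "std_error"),
      by = c("time", "node")
    )
}

#' @export
glance.ensemble_result <- function(x, ...) {
  ap <- asymptotic_probabilities(x)
  tibble::tibble(
    n_trajectories = x$n_trajectories,
    n_nodes = length(x$nodes),
    max_time = x$max_time,
    median_asymptotic_se = stats::median(asymptotic_window_se(x))
  ) %>%
    dplyr::bind_cols(tidyr::pivot_wider(ap, names_from = "node",
                                        values_from = "probability"))
}

# bins covered by the trailing asymptotic window
asymptotic_bins <- function(x, window = x$asymptotic_window) {
  cutoff <- (1 - window) * x$max_time
  sel <- which(x$breaks[-length(x$breaks)] >= cutoff - 1e-9)
  if (length(sel) == 0L) sel <- length(x$times)
  sel
}

asymptotic_window_se <- function(x) {
  sel <- asymptotic_bins(x)
  apply(x$node_se[sel, , drop = FALSE], 2, stats::median)
}

#' Asymptotic node or state probabilities of an ensemble
#'
#' Time-average of the per-bin estimates over the trailing
#' `asymptotic_window` fraction of the simulated horizon. Late-time
#' averages are closer to the attractor structure of the model than any
#' single transient bin and are the quantity used for phenotype read-outs.
#'
#' @param result an `ensemble_result`.
#' @param what `"nodes"` (default) for per-node activation probabilities,
#'   `"states"` for model-state probabilities (requires state recording).
#' @param window override the trailing window fraction.
#' @return tibble of `node`/`state` and `probability`.
#' @export
asymptotic_probabilities <- function(result, what = c("nodes", "states"),
                                     window = NULL) {
  what <- match.arg(what)
  if (is.null(window)) window <- result$asymptotic_window
  if (!(window > 0 && window <= 1)) stop("empty asymptotic window", call. = FALSE)
  sel <- asymptotic_bins(result, window)
  if (what == "nodes") {
    p <- colMeans(result$node_prob[sel, , drop = FALSE])
    return(tibble::tibble(node = result$nodes, probability = unname(p)))
  }
  if (is.null(result$states))
    stop("state probabilities were not recorded for this ensemble", call. = FALSE)
  result$states %>%
    dplyr::filter(.data$bin %in% sel) %>%
    dplyr::group_by(.data$state_key) %>%
    dplyr::summarise(probability = sum(.data$probability) / length(sel),
                     .groups = "drop") %>%
    dplyr::mutate(state = state_key_label(.data$state_key, result$nodes),
                  .before = 1)
}

# human-readable label for a packed model state (active nodes joined by " ")
state_key_label <- function(key, nodes) {
  vapply(key, function(k) {
    act <- nodes[bit_is_set(k, seq_along(nodes))]
    if (length(act) == 0L) "<nil>" else paste(act, collapse = " ")
  }, character(1))
}

bit_is_set <- function(key, i) (key %/% 2^(i - 1)) %% 2 >= 1

# ---------------------------------------------------------------------------
# Exact master-equation oracle
# ---------------------------------------------------------------------------

#' Exact transient distribution of a small model
#'
#' Solves the continuous-time master equation on the full 2^n state space:
#' the sparse generator is built from the enabled transitions of every
#' state, and the transient solution at time `t` is computed by
#' uniformization. Serves as an independent oracle for the stochastic
#' engine; practical up to `max_nodes` nodes and rate-time products of
#' moderate size.
#'
#' @inheritParams enabled_transitions
#' @param t time (scalar) at which to evaluate the distribution.
#' @param max_nodes refuse models larger than this (default 12).
#' @return tibble with `state_key`, `state` label and `probability`
#'   (summing to 1).
#' @export
exact_distribution <- function(model, settings, t, max_nodes = 12L) {
  validate_model(model, settings)
  n <- length(model$nodes)
  if (n > max_nodes)
    stop(sprintf("model has %d nodes; the exact oracle is limited to %d",
                 n, max_nodes), call. = FALSE)
  gen <- build_generator(model, settings)
  p0 <- initial_distribution(settings, model$nodes)
  p <- uniformization(p0, gen$Q, t)
  tibble::tibble(
    state_key = as.numeric(0:(2^n - 1)),
    state = state_key_label(as.numeric(0:(2^n - 1)), model$nodes),
    probability = p
  )
}

#' Exact node marginals over a set of times
#'
#' Convenience wrapper around [exact_distribution()] evaluating
#' `P(node = 1)` at each requested time.
#'
#' @inheritParams exact_distribution
#' @param times numeric vector of times.
#' @return tibble with `time`, `node`, `probability`.
#' @export
exact_node_marginals <- function(model, settings, times, max_nodes = 12L) {
  n <- length(model$nodes)
  if (n > max_nodes)
    stop(sprintf("model has %d nodes; the exact oracle is limited to %d",
                 n, max_nodes), call. = FALSE)
  gen <- build_generator(model, settings)
  p0 <- initial_distribution(settings, model$nodes)
  keys <- 0:(2^n - 1)
  bits <- vapply(seq_len(n), function(i) bit_is_set(keys, i), logical(2^n))
  purrr::map_dfr(times, function(t) {
    p <- uniformization(p0, gen$Q, t)
    tibble::tibble(time = t, node = model$nodes,
                   probability = as.numeric(crossprod(bits, p)))
  })
}

# sparse generator Q with Q[s, s'] the rate of the s -> s' transition
build_generator <- function(model, settings) {
  n <- length(model$nodes)
  n_states <- 2^n
  keys <- 0:(n_states - 1)
  states <- vapply(seq_len(n), function(i) as.integer(bit_is_set(keys, i)),
                   integer(n_states))
  codes <- compile_rules(model)
  ord <- match(model$nodes, settings$nodes$node)
  k_up <- settings$nodes$k_up[ord]
  k_down <- settings$nodes$k_down[ord]
  from <- integer(0); to <- integer(0); rate <- numeric(0)
  for (i in seq_len(n)) {
    target <- eval_rule_matrix(codes[[i]], states)
    cur <- states[, i] == 1L
    up <- !cur & target
    dn <- cur & !target
    if (k_up[i] > 0 && any(up)) {
      s <- which(up)
      from <- c(from, s); to <- c(to, s + 2^(i - 1))
      rate <- c(rate, rep(k_up[i], length(s)))
    }
    if (k_down[i] > 0 && any(dn)) {
      s <- which(dn)
      from <- c(from, s); to <- c(to, s - 2^(i - 1))
      rate <- c(rate, rep(k_down[i], length(s)))
    }
  }
  Q <- Matrix::sparseMatrix(i = from, j = to, x = rate,
                            dims = c(n_states, n_states))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  list(Q = Q, states = states)
}

initial_distribution <- function(settings, nodes) {
  n <- length(nodes)
  istate <- settings$nodes$istate[match(nodes, settings$nodes$node)]
  keys <- 0:(2^n - 1)
  p0 <- rep(1, 2^n)
  for (i in seq_len(n)) {
    on <- bit_is_set(keys, i)
    p0 <- p0 * ifelse(on, istate[i], 1 - istate[i])
  }
  p0
}

# p(t) = sum_k Pois(k; Lambda t) p0 P^k with P = I + Q / Lambda
uniformization <- function(p0, Q, t, tol = 1e-12) {
  if (t < 0) stop("time must be nonnegative", call. = FALSE)
  lambda <- max(-Matrix::diag(Q))
  if (t == 0 || lambda <= 0) return(p0)
  lt <- lambda * t
  if (lt > 2e5)
    stop("rate-time product too large for the uniformization oracle", call. = FALSE)
  K <- stats::qpois(tol, lt, lower.tail = FALSE) + 5L
  P <- Matrix::Diagonal(nrow(Q)) + Q / lambda
  # Poisson weights computed in log space to survive large lt
  lw <- stats::dpois(0:K, lt, log = TRUE)
  w <- exp(lw)
  pk <- p0
  acc <- w[1] * pk
  for (k in seq_len(K)) {
    pk <- as.numeric(pk %*% P)
    acc <- acc + w[k + 1] * pk
  }
  acc <- pmax(acc, 0)
  acc / sum(acc)
}
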