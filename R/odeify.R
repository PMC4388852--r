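## ---- Hill-type ODE translation ---------------------------------------------
## Each Boolean rule f is extended to the unit cube by multilinear
## interpolation (matching f exactly on 0/1 vertices); inputs are passed
## through normalized Hill functions, and every node relaxes towards its
## (continuous) rule value on its own timescale:
##   dx_i/dt = (ftilde_i(h(x_i1), ..., h(x_ik)) - x_i) / tau_i

#' Multilinear (boolecube) extension of an update rule
#'
#' Interpolates the rule's truth table over the unit cube:
#' `f(x) = sum_v f(v) prod_j [x_j v_j + (1-x_j)(1-v_j)]`, which agrees with
#' the Boolean rule at every 0/1 vertex.
#'
#' @param net a [boolean_network()] object.
#' @param node regulated node name.
#' @return function taking a numeric vector over the rule's inputs (in
#'   network node order; see attribute `"inputs"`) and returning a value
#'   in `[0, 1]`.
#' @examples
#' net <- bn_parse("C* = A and B")
#' f <- boolecube(net, "C")
#' f(c(0.5, 0.5))   # 0.25
#' @export
boolecube <- function(net, node) {
  tt <- rule_truth_table(net, node)
  f <- function(x) .multilinear(tt$tt, x)
  attr(f, "inputs") <- tt$inputs
  f
}

.multilinear <- function(ttvec, x) {
  v <- as.numeric(ttvec)
  for (j in seq_along(x)) {
    odd <- v[seq(1L, length(v), by = 2L)]
    even <- v[seq(2L, length(v), by = 2L)]
    v <- odd * (1 - x[[j]]) + even * x[[j]]
  }
  v
}

#' Hill function parameters for the ODE translation
#'
#' @param n Hill coefficient (>= 1); steepness of the sigmoidal response.
#' @param theta response threshold in (0, 1); the unnormalized Hill
#'   function crosses 1/2 at `theta`.
#' @param tau node timescale (> 0), the relaxation time of each node.
#'   `n`, `theta` and `tau` may be scalars or named vectors (per node for
#'   `tau`; per node for `n` and `theta`, applied to all of that node's
#'   inputs).
#' @param normalized if TRUE (default) Hill responses are rescaled by
#'   `h(1)` so the continuous rules agree with the Boolean rules exactly
#'   on all 0/1 vertices, preserving every Boolean fixed point.
#' @return list of class `hill_params`.
#' @export
hill_params <- function(n = 3, theta = 0.5, tau = 1, normalized = TRUE) {
  stopifnot(all(n >= 1), all(theta > 0), all(theta < 1), all(tau > 0))
  structure(list(n = n, theta = theta, tau = tau, normalized = normalized),
            class = "hill_params")
}

.param_for <- function(p, node, default) {
  if (is.null(names(p))) return(p[[1L]])
  if (node %in% names(p)) p[[node]] else default
}

.hill <- function(x, n, theta, normalized) {
  x <- pmin(pmax(x, 0), 1)
  h <- x^n / (x^n + theta^n)
  if (normalized) h / (1 / (1 + theta^n)) else h
}

#' Hill-sigmoid (hillcube) extension of an update rule
#'
#' As [boolecube()], but each input is first passed through a Hill
#' function `h(x) = x^n / (x^n + theta^n)` (divided by `h(1)` when
#' normalized, so 0/1 vertex agreement with the Boolean rule is exact).
#'
#' @inheritParams boolecube
#' @param params a [hill_params()] object.
#' @return function as in [boolecube()].
#' @export
hillcube <- function(net, node, params = hill_params()) {
  tt <- rule_truth_table(net, node)
  n <- .param_for(params$n, node, 3)
  theta <- .param_for(params$theta, node, 0.5)
  normalized <- isTRUE(params$normalized)
  f <- function(x) .multilinear(tt$tt, .hill(x, n, theta, normalized))
  attr(f, "inputs") <- tt$inputs
  f
}

#' Translate a Boolean network into a Hill-type ODE model
#'
#' Every regulated node obeys `dx/dt = (ftilde(x_in) - x)/tau` with
#' `ftilde` the (normalized) Hill-sigmoid extension of its rule; input
#' nodes are held at their environment value.  With normalized Hill
#' functions every Boolean fixed point is an equilibrium of the ODE model,
#' and the unit cube is forward-invariant.
#'
#' @param net a [boolean_network()] with environment resolved.
#' @param params a [hill_params()] object.
#' @return object of class `ode_model`.
#' @export
build_ode_model <- function(net, params = hill_params()) {
  stopifnot(inherits(net, "boolean_network"))
  .check_environment(net)
  nodes <- net$nodes
  nidx <- setNames(seq_along(nodes), nodes)
  comp <- lapply(nodes, function(nm) {
    if (!nm %in% names(net$rules)) return(NULL)
    tt <- rule_truth_table(net, nm)
    list(tt = as.numeric(tt$tt), idx = unname(nidx[tt$inputs]),
         n = .param_for(params$n, nm, 3),
         theta = .param_for(params$theta, nm, 0.5),
         tau = .param_for(params$tau, nm, 1))
  })
  names(comp) <- nodes
  env_val <- rep(NA_real_, length(nodes))
  for (nm in names(net$environment)) env_val[[nidx[[nm]]]] <- net$environment[[nm]]
  normalized <- isTRUE(params$normalized)
  rhs <- function(t, state, clamp_idx = integer(0)) {
    dx <- numeric(length(state))
    for (i in seq_along(state)) {
      ci <- comp[[i]]
      if (is.null(ci)) next   # environment input: constant
      v <- .multilinear(ci$tt, .hill(state[ci$idx], ci$n, ci$theta, normalized))
      dx[[i]] <- (v - state[[i]]) / ci$tau
    }
    if (length(clamp_idx)) dx[clamp_idx] <- 0
    dx
  }
  structure(list(network = net, nodes = nodes, params = params,
                 rhs = rhs, env_val = env_val),
            class = "ode_model")
}

#' @export
print.ode_model <- function(x, ...) {
  cat(sprintf("Hill-type ODE model: %d state variables (n = %s, theta = %s, %s)\n",
              length(x$nodes),
              paste(unique(x$params$n), collapse = "/"),
              paste(unique(x$params$theta), collapse = "/"),
              if (isTRUE(x$params$normalized)) "normalized" else "unnormalized"))
  invisible(x)
}

#' Right-hand-side residual at a state
#'
#' @param model an `ode_model`.
#' @param state named (or ordered) numeric vector over the model's nodes.
#' @return max absolute time-derivative; ~0 at an equilibrium.
#' @export
ode_residual <- function(model, state) {
  stopifnot(inherits(model, "ode_model"))
  if (!is.null(names(state))) state <- state[model$nodes]
  max(abs(model$rhs(0, as.numeric(state))))
}

#' ODE simulation configuration
#'
#' @param n_ic number of uniformly random initial vectors in `[0,1]^N`.
#' @param t_end integration horizon per phase (time units; the default 500
#'   is many node timescales).
#' @param seed integer seed.
#' @param rtol relative tolerance of the adaptive (stiff-safe) integrator.
#' @param conv_tol slope criterion: an endpoint with max |dx/dt| above
#'   this is counted unresolved rather than classified.
#' @return list of class `ode_config`.
#' @export
ode_config <- function(n_ic = 100, t_end = 500, seed = 1L, rtol = 1e-6,
                       conv_tol = 1e-3) {
  structure(list(n_ic = as.integer(n_ic), t_end = t_end,
                 seed = as.integer(seed), rtol = rtol, conv_tol = conv_tol),
            class = "ode_config")
}

## integrate one trajectory (one or two phases); returns the final state
.ode_run_one <- function(model, x0, interv, config) {
  clamp_idx <- integer(0)
  if (length(interv$states)) {
    clamp_idx <- match(names(interv$states), model$nodes)
    x0[clamp_idx] <- attr(interv, "clamp_values") %||% unname(interv$states)
  }
  phases <- if (identical(interv$mode, "transient") && length(clamp_idx))
    list(clamp_idx, integer(0)) else list(clamp_idx)
  x <- x0
  for (ph in phases) {
    out <- deSolve::lsoda(
      y = x, times = c(0, config$t_end),
      func = function(t, y, p) list(model$rhs(t, y, ph)),
      rtol = config$rtol, atol = config$rtol)
    x <- as.numeric(out[nrow(out), -1L])
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate attractor probabilities in the ODE model
#'
#' Integrates uniformly random initial vectors (environment inputs at
#' their environment value; clamped nodes held at the intervention value,
#' or at `clamp_values` for near-value clamping).  The endpoint is
#' classified by the quasi-attractor whose fixed part it matches with
#' every coordinate on the correct side of 0.5; endpoints still moving
#' (slope above `conv_tol`) or matching no attractor are unresolved.
#'
#' @param model an `ode_model` from [build_ode_model()].
#' @param attractors list of `quasi_attractor` objects.
#' @param interv an [intervention()]; set attribute `clamp_values` on it
#'   to clamp near (not exactly at) the prescribed 0/1 values.
#' @param config an [ode_config()].
#' @param markers optional phenotype markers used as a fallback
#'   classification as in [estimate_attractor_probabilities()].
#' @return an `attractor_probabilities` object.
#' @export
ode_attractor_probabilities <- function(model, attractors,
                                        interv = intervention(),
                                        config = ode_config(),
                                        markers = NULL) {
  stopifnot(inherits(model, "ode_model"))
  nodes <- model$nodes
  am <- .attractor_matrix(model$network, attractors)
  labels <- vapply(attractors, function(a) a$label, character(1))
  if (!is.null(markers) && length(markers)) {
    mm <- matrix(-1L, nrow = length(markers), ncol = length(nodes),
                 dimnames = list(NULL, nodes))
    for (k in seq_along(markers))
      mm[k, names(markers[[k]])] <- .parse_state_value(markers[[k]])
    am <- rbind(am, mm)
    labels <- c(labels, names(markers))
  }
  set.seed(config$seed)
  labs <- character(config$n_ic)
  for (ic in seq_len(config$n_ic)) {
    x0 <- runif(length(nodes))
    fixed <- !is.na(model$env_val)
    x0[fixed] <- model$env_val[fixed]
    x <- tryCatch(.ode_run_one(model, x0, interv, config),
                  error = function(e) NULL)
    if (is.null(x)) { labs[[ic]] <- "unresolved"; next }
    slope_clamp <- if (identical(interv$mode, "permanent") &&
                       length(interv$states))
      match(names(interv$states), nodes) else integer(0)
    if (max(abs(model$rhs(0, x, slope_clamp))) > config$conv_tol) {
      labs[[ic]] <- "unresolved"; next
    }
    bits <- as.integer(x > 0.5)
    hit <- "unresolved"
    for (a in seq_len(nrow(am))) {
      sel <- am[a, ] >= 0
      if (all(am[a, sel] == bits[sel])) { hit <- labels[[a]]; break }
    }
    labs[[ic]] <- hit
  }
  ulab <- unique(labels)
  p <- vapply(ulab, function(l) mean(labs == l), numeric(1))
  df <- data.frame(label = ulab, p = p,
                   se = sqrt(p * (1 - p) / config$n_ic),
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(df, class = c("attractor_probabilities", "data.frame"),
            unresolved = mean(labs == "unresolved"), n_ic = config$n_ic)
}

#' Effectiveness sweep over Hill parameters
#'
#' Re-estimates the probability of reaching a target attractor under an
#' intervention for each Hill coefficient (optionally with randomized
#' timescales and thresholds), reporting how robust the intervention is to
#' the continuous model's kinetic parameters.
#'
#' @param net a [boolean_network()] with environment resolved.
#' @param attractors list of `quasi_attractor` objects.
#' @param target target attractor label.
#' @param interv an [intervention()].
#' @param n_values Hill coefficients to sweep (default `c(2, 3, 5, 10)`).
#' @param randomize if TRUE, draw per-node tau in `[0.5, 2]` and theta in
#'   `[0.3, 0.7]` for each sweep point.
#' @param config an [ode_config()].
#' @param markers optional phenotype markers.
#' @return data.frame: n, effectiveness (probability of the target), and
#'   unresolved fraction.
#' @export
ode_parameter_sweep <- function(net, attractors, target, interv,
                                n_values = c(2, 3, 5, 10),
                                randomize = FALSE,
                                config = ode_config(), markers = NULL) {
  rows <- list()
  for (nv in n_values) {
    set.seed(config$seed + nv)
    reg <- names(net$rules)
    params <- if (randomize)
      hill_params(n = nv,
                  theta = setNames(runif(length(reg), 0.3, 0.7), reg),
                  tau = setNames(runif(length(reg), 0.5, 2), reg))
    else hill_params(n = nv)
    model <- build_ode_model(net, params)
    est <- ode_attractor_probabilities(model, attractors, interv, config,
                                       markers)
    rows[[length(rows) + 1L]] <- data.frame(
      n = nv,
      effectiveness = est$p[est$label == target],
      unresolved = attr(est, "unresolved"))
  }
  do.call(rbind, rows)
}
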