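## ---- general asynchronous simulation and intervention validation -----------

#' Simulation configuration
#'
#' Default budgets follow the validation protocol of the underlying method:
#' 50,000 update steps per evolution stage and 100,000 initial conditions
#' give three significant digits in the estimated probabilities; the
#' desk-scale preset (`sim_config(n_ic = 1e4, steps = 1e4)`) is sufficient
#' for the case-study networks at reduced precision.
#'
#' @param n_ic number of uniformly random initial conditions.
#' @param steps update steps per evolution stage.
#' @param seed integer seed; every random draw derives from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_ic = 1e5, steps = 5e4, seed = 1L) {
  stopifnot(n_ic >= 1, steps >= 1)
  structure(list(n_ic = as.integer(n_ic), steps = steps,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Specify an intervention
#'
#' @param states named vector of clamped node states (0/1/ON/OFF).  An
#'   empty intervention is the no-intervention baseline.
#' @param mode `"permanent"` (clamps held throughout) or `"transient"`
#'   (clamps held for one evolution stage, then released for a second
#'   stage before the attractor is read off).
#' @return list of class `intervention`.
#' @export
intervention <- function(states = integer(0), mode = c("permanent", "transient")) {
  mode <- match.arg(mode)
  if (length(states)) {
    vals <- .parse_state_value(states)
    names(vals) <- names(states)
    if (anyDuplicated(names(vals)))
      stop("inconsistent intervention: duplicated node names")
    states <- vals
  }
  structure(list(states = states, mode = mode), class = "intervention")
}

## compile a network (environment resolved) for the C++ simulator
.compile_for_sim <- function(net) {
  .check_environment(net)
  nodes <- net$nodes
  nidx <- setNames(seq_along(nodes) - 1L, nodes)
  inputs <- vector("list", length(nodes))
  tts <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    nm <- nodes[[i]]
    if (nm %in% names(net$rules)) {
      tt <- rule_truth_table(net, nm)
      inputs[[i]] <- unname(nidx[tt$inputs])
      tts[[i]] <- tt$tt
    } else {
      inputs[[i]] <- integer(0)
      tts[[i]] <- net$environment[[nm]]
    }
  }
  list(nodes = nodes, inputs = inputs, tts = tts)
}

## attractor fixed parts as a matrix over network nodes; -1 = ignore (OSC)
.attractor_matrix <- function(net, attractors) {
  m <- matrix(-1L, nrow = length(attractors), ncol = length(net$nodes),
              dimnames = list(NULL, net$nodes))
  for (a in seq_along(attractors)) {
    st <- attractors[[a]]$states
    m[a, names(st)] <- st
  }
  m
}

#' Perform one general-asynchronous update step
#'
#' One node, chosen uniformly at random (using R's RNG), is updated by its
#' rule; all other nodes retain their state.
#'
#' @param net a [boolean_network()] object with environment resolved.
#' @param state named complete 0/1 state.
#' @return the new state (named integer vector).
#' @export
async_step <- function(net, state) {
  stopifnot(inherits(net, "boolean_network"))
  vals <- .parse_state_value(state)
  names(vals) <- names(state)
  missing <- setdiff(net$nodes, names(vals))
  if (length(missing))
    stop("incomplete state; missing: ", paste(missing, collapse = ", "))
  i <- sample.int(length(net$nodes), 1L)
  nm <- net$nodes[[i]]
  vals[[nm]] <- bn_evaluate(net, nm, vals)
  vals
}

#' Evolve one initial condition to an attractor label
#'
#' Runs the general asynchronous dynamics (with the intervention's nodes
#' clamped while it is active) for the configured number of steps per
#' stage, then matches the final state against each quasi-attractor's
#' fixed part (OSC nodes ignored).
#'
#' @param net a [boolean_network()] object with environment resolved.
#' @param initial named complete 0/1 state.
#' @param attractors list of `quasi_attractor` (from [quasi_attractors()]).
#' @param interv an [intervention()]; defaults to none.
#' @param config a [sim_config()].
#' @param markers optional phenotype markers used as fallback
#'   classification (see [estimate_attractor_probabilities()]).
#' @return the matched attractor's label, or `"unresolved"`.
#' @export
run_to_attractor <- function(net, initial, attractors,
                             interv = intervention(), config = sim_config(),
                             markers = NULL) {
  comp <- .compile_for_sim(net)
  vals <- .parse_state_value(initial)
  names(vals) <- names(initial)
  init <- matrix(vals[comp$nodes], nrow = 1)
  lab <- .sim_labels(comp, net, attractors, interv, config, init, markers)
  lab[[1L]]
}

.sim_labels <- function(comp, net, attractors, interv, config, init = NULL,
                        markers = NULL) {
  am <- .attractor_matrix(net, attractors)
  labels <- vapply(attractors, function(a) a$label, character(1))
  ## trajectories ending in a state matching no quasi-attractor exactly
  ## (e.g. under an attractor-destroying blocking intervention) fall back
  ## to the phenotype specification: marker nodes only
  if (!is.null(markers) && length(markers)) {
    mm <- matrix(-1L, nrow = length(markers), ncol = length(net$nodes),
                 dimnames = list(NULL, net$nodes))
    for (k in seq_along(markers)) {
      mk <- .parse_state_value(markers[[k]])
      mm[k, names(markers[[k]])] <- mk
    }
    am <- rbind(am, mm)
    labels <- c(labels, names(markers))
  }
  cidx <- integer(0); cval <- integer(0)
  if (length(interv$states)) {
    unknown <- setdiff(names(interv$states), comp$nodes)
    if (length(unknown))
      stop("intervention names not in network: ",
           paste(unknown, collapse = ", "))
    cidx <- match(names(interv$states), comp$nodes) - 1L
    cval <- unname(interv$states)
  }
  two_stage <- identical(interv$mode, "transient") && length(cidx)
  labs <- cpp_simulate_labels(
    comp$inputs, comp$tts, am, cidx, cval,
    steps_clamped = config$steps,
    steps_free = if (two_stage) config$steps else 0,
    n_ic = if (is.null(init)) config$n_ic else nrow(init),
    seed = config$seed,
    init = init)
  out <- c("unresolved", labels)
  out[labs + 1L]
}

#' Estimate attractor probabilities under an intervention
#'
#' Evolves uniformly random initial conditions (environment inputs held at
#' their environment state) and reports, per attractor label, the fraction
#' of initial conditions that reach it, with the binomial standard error
#' sqrt(p(1-p)/n_ic), plus the unresolved fraction (trajectories matching
#' no attractor within the step budget).  Fully seed-reproducible.
#'
#' @param net a [boolean_network()] object with environment resolved.
#' @param attractors list of `quasi_attractor` objects.
#' @param interv an [intervention()].
#' @param config a [sim_config()].
#' @param markers optional named list of phenotype marker partial states;
#'   a final state matching no quasi-attractor exactly is then classified
#'   by its marker nodes alone, mirroring validation of interventions that
#'   eliminate an attractor but leave states satisfying its biological
#'   specification.
#' @return object of class `attractor_probabilities`: data.frame with
#'   columns label, p, se, plus attributes `unresolved` and `n_ic`.
#' @export
estimate_attractor_probabilities <- function(net, attractors,
                                             interv = intervention(),
                                             config = sim_config(),
                                             markers = NULL) {
  comp <- .compile_for_sim(net)
  labs <- .sim_labels(comp, net, attractors, interv, config,
                      markers = markers)
  labels <- unique(c(vapply(attractors, function(a) a$label, character(1)),
                     names(markers)))
  counts <- vapply(labels, function(l) sum(labs == l), numeric(1))
  n <- length(labs)
  p <- counts / n
  df <- data.frame(label = labels, p = p, se = sqrt(p * (1 - p) / n),
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(df, class = c("attractor_probabilities", "data.frame"),
            unresolved = sum(labs == "unresolved") / n, n_ic = n)
}

#' @export
print.attractor_probabilities <- function(x, ...) {
  cat(sprintf("Attractor probabilities (n_ic = %d):\n", attr(x, "n_ic")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-14s %6.2f%%  (se %.3f%%)\n",
                x$label[[i]], 100 * x$p[[i]], 100 * x$se[[i]]))
  if (attr(x, "unresolved") > 0)
    cat(sprintf("  %-14s %6.2f%%\n", "unresolved",
                100 * attr(x, "unresolved")))
  invisible(x)
}

#' Validate interventions against a baseline, mirroring the published
#' validation tables
#'
#' For each intervention, estimates attractor probabilities and reports the
#' per-attractor percentage, its standard error, and the relative change
#' (attractor % - normal attractor %) / (normal attractor %) against the
#' no-intervention baseline.
#'
#' @param net a [boolean_network()] with environment resolved.
#' @param attractors list of `quasi_attractor` objects.
#' @param interventions list of [intervention()] objects (named, optionally).
#' @param config a [sim_config()].
#' @param path optional TSV output file.
#' @param markers optional phenotype markers (see
#'   [estimate_attractor_probabilities()]).
#' @return data.frame with one row per intervention x attractor.
#' @export
validation_report <- function(net, attractors, interventions,
                              config = sim_config(), path = "",
                              markers = NULL) {
  base <- estimate_attractor_probabilities(net, attractors,
                                           intervention(), config, markers)
  rows <- list()
  for (k in seq_along(interventions)) {
    iv <- interventions[[k]]
    est <- estimate_attractor_probabilities(net, attractors, iv, config,
                                            markers)
    nm <- if (!is.null(names(interventions)) &&
              nzchar(names(interventions)[[k]])) names(interventions)[[k]]
          else if (length(iv$states))
            paste(sprintf("%s=%s", names(iv$states),
                          ifelse(iv$states == 1L, "ON", "OFF")),
                  collapse = ",")
          else "baseline"
    for (i in seq_len(nrow(est))) {
      p0 <- base$p[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        intervention = nm, mode = iv$mode,
        attractor = est$label[[i]],
        percent = 100 * est$p[[i]], se_percent = 100 * est$se[[i]],
        baseline_percent = 100 * p0,
        relative_change = if (p0 > 0) (est$p[[i]] - p0) / p0 else NA_real_,
        unresolved_percent = 100 * attr(est, "unresolved"),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  if (nzchar(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
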