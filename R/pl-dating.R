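# Penalized-likelihood divergence dating.
#
# Branch "substitution counts" (branch length x alignment sites, rounded)
# are modeled as Poisson with mean rate x duration x sites; node ages and
# per-branch rates maximize the Poisson log-likelihood minus a smoothing
# penalty on rate changes between adjacent branches (squared differences of
# log-rates parent-to-child, plus the sum of squared deviations of the
# root's child-branch log-rates from their mean). Ages respect a fixed root
# calibration and any minimum-age constraints by construction: each free
# node's age is its subtree lower bound plus a logistic fraction of the
# span up to its parent's age.

#' Build a calibration set
#'
#' @param tips List (or ";"-separated strings) of tip labels whose MRCA is
#'   calibrated.
#' @param kind "fixed" or "min" per calibration.
#' @param age Ages in mya (> 0).
#' @return A `calibration_set` data frame.
#' @export
calibration_set <- function(tips, kind, age) {
  if (is.character(tips)) tips <- strsplit(tips, ";", fixed = TRUE)
  stopifnot(all(kind %in% c("fixed", "min")), all(age > 0),
            length(tips) == length(kind), length(kind) == length(age))
  structure(data.frame(kind = kind, age = age, stringsAsFactors = FALSE,
                       tips = I(tips)),
            class = c("calibration_set", "data.frame"))
}

# resolve calibration nodes, lower bounds, and fixed ages for a tree
resolve_calibrations <- function(tree, calib) {
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  root <- ntip + 1L
  fixed <- rep(NA_real_, ntot)
  minb <- rep(0, ntot)
  for (i in seq_len(nrow(calib))) {
    tips <- match(calib$tips[[i]], tree$tip.label)
    if (any(is.na(tips))) stop("calibration tip not in tree")
    node <- if (length(tips) == 1) tips else ape::getMRCA(tree, tips)
    if (calib$kind[i] == "fixed") fixed[node] <- calib$age[i]
    else minb[node] <- max(minb[node], calib$age[i])
  }
  if (is.na(fixed[root])) stop("the root calibration must be fixed")
  list(fixed = fixed, minb = minb, root = root, ntip = ntip, ntot = ntot)
}

#' Date a tree by penalized-likelihood rate smoothing
#'
#' @param tree Rooted binary ape phylo with branch lengths in
#'   substitutions/site and (optionally) bootstrap node labels.
#' @param n_sites Alignment length used to convert branch lengths to
#'   substitution counts.
#' @param calib A [calibration_set()]; must fix the root age.
#' @param lambda Smoothing parameter (>= 0); large values force a clock.
#' @param n_starts Optimizer restarts (first start is deterministic).
#' @param seed Integer seed for the random restarts.
#' @param control Control list passed to [stats::optim()] (L-BFGS-B); the
#'   tight default `factr = 1` resolves the flat likelihood valley down to
#'   the penalty scale.
#' @return A `dated_tree`: `ages` (per node, mya; names are sorted
#'   clade tip sets), `node_ages` (by ape node number), `rates` (per edge,
#'   substitutions/site/mya), `lambda`, `objective`, `convergence`,
#'   `tree` (input), `chronogram` (phylo with edge lengths in mya).
#' @export
pl_date <- function(tree, n_sites, calib, lambda = 1, n_starts = 5L,
                    seed = 1L, control = list(maxit = 5000, factr = 1)) {
  stopifnot(ape::is.rooted(tree), !is.null(tree$edge.length),
            all(is.finite(tree$edge.length)), n_sites >= 1, lambda >= 0)
  cal <- resolve_calibrations(tree, calib)
  prob <- pl_problem(tree, n_sites, cal, lambda)

  fits <- with_seed(seed, lapply(seq_len(n_starts), function(s) {
    par0 <- prob$init(random = s > 1)
    tryCatch(
      stats::optim(par0, fn = prob$fn, gr = prob$gr, method = "L-BFGS-B",
                   lower = prob$lower, upper = prob$upper,
                   control = control),
      error = function(e) NULL)
  }))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("optimization failed in every start")
  # near-ties go to the earliest (deterministic) start: along the flat
  # rate-age compensation valley, objective differences below numerical
  # resolution should not override the structured initialization
  vals <- vapply(fits, `[[`, 0, "value")
  best <- fits[[which(vals <= min(vals) + 1e-8 + 1e-8 * abs(min(vals)))[1]]]

  sol <- prob$decode(best$par)
  ntip <- cal$ntip
  keys <- vapply(tips_by_node(tree), function(tt)
    paste(sort(tree$tip.label[tt]), collapse = "|"), "")
  ages <- stats::setNames(sol$ages, keys)

  # hard post-conditions: ordering and calibrations
  parent_age <- sol$ages[tree$edge[, 1]]
  child_age <- sol$ages[tree$edge[, 2]]
  stopifnot(all(parent_age - child_age > -1e-9))
  fixed_nodes <- which(!is.na(cal$fixed))
  stopifnot(all(abs(sol$ages[fixed_nodes] - cal$fixed[fixed_nodes]) < 1e-9))
  stopifnot(all(sol$ages - cal$minb > -1e-9))

  chrono <- tree
  chrono$edge.length <- parent_age - child_age
  structure(list(ages = ages[-seq_len(ntip)], node_ages = sol$ages,
                 rates = sol$rates, lambda = lambda,
                 objective = -best$value,
                 convergence = best$convergence, n_starts_ok = length(fits),
                 tree = tree, chronogram = chrono),
            class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("dated_tree: lambda =", x$lambda, " objective =",
      format(x$objective), "\n")
  print(round(x$ages, 4))
  invisible(x)
}

# assemble the objective, analytic gradient, bounds, and decoders
pl_problem <- function(tree, n_sites, cal, lambda) {
  ntip <- cal$ntip; ntot <- cal$ntot; root <- cal$root
  edge <- tree$edge
  x <- pmax(0, round(tree$edge.length * n_sites))  # substitution counts

  parent <- integer(ntot); parent[edge[, 2]] <- edge[, 1]
  children <- split(edge[, 2], factor(edge[, 1], levels = seq_len(ntot)))

  # subtree lower bounds (own min bound, fixed ages below, via postorder)
  lbs <- cal$minb
  lbs[which(!is.na(cal$fixed))] <-
    pmax(lbs[which(!is.na(cal$fixed))], cal$fixed[which(!is.na(cal$fixed))])
  po <- edge[ape::postorder(tree), , drop = FALSE]
  for (e in seq_len(nrow(po)))
    lbs[po[e, 1]] <- max(lbs[po[e, 1]], lbs[po[e, 2]])
  # feasibility: every fixed age must dominate its subtree lower bounds
  for (v in which(!is.na(cal$fixed)))
    if (cal$fixed[v] < max(lbs[unlist(children[[v]])], 0))
      stop("infeasible calibrations: a minimum exceeds a fixed ancestor age")

  # preorder over internal nodes (root first)
  pre <- integer(0); queue <- root
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    pre <- c(pre, v)
    kids <- children[[v]]
    queue <- c(queue, kids[kids > ntip])
  }
  free <- pre[is.na(cal$fixed[pre])]
  nfree <- length(free)
  nedge <- nrow(edge)
  free_idx <- stats::setNames(seq_along(free), free)

  compute_ages <- function(theta, jacobian = FALSE) {
    ages <- numeric(ntot)
    J <- if (jacobian) matrix(0, ntot, nfree) else NULL
    for (v in pre) {
      if (!is.na(cal$fixed[v])) { ages[v] <- cal$fixed[v]; next }
      pa <- parent[v]
      lb <- lbs[v]
      m <- free_idx[[as.character(v)]]
      f <- stats::plogis(theta[m])
      ages[v] <- lb + f * (ages[pa] - lb)
      if (jacobian) {
        J[v, ] <- f * J[pa, ]
        J[v, m] <- J[v, m] + f * (1 - f) * (ages[pa] - lb)
      }
    }
    list(ages = ages, J = J)
  }

  # penalty bookkeeping: parent-child edge pairs and root child edges
  edge_of_child <- stats::setNames(seq_len(nedge), edge[, 2])
  pair_a <- integer(0); pair_b <- integer(0)
  for (b in seq_len(nedge)) {
    v <- edge[b, 2]
    if (v > ntip)
      for (cv in children[[v]]) {
        pair_a <- c(pair_a, b)
        pair_b <- c(pair_b, edge_of_child[[as.character(cv)]])
      }
  }
  root_edges <- vapply(children[[root]],
                       function(cv) edge_of_child[[as.character(cv)]], 0L)


  eval_all <- function(par, grad = FALSE) {
    theta <- par[seq_len(nfree)]
    logr <- par[nfree + seq_len(nedge)]
    ag <- compute_ages(theta, jacobian = grad)
    dur <- pmax(ag$ages[edge[, 1]] - ag$ages[edge[, 2]], 1e-12)
    mu <- exp(logr) * dur * n_sites
    # log-likelihood centered at its saturated maximum, evaluated per edge as
    # x log1p((mu-x)/x) + (x-mu): near the optimum every term is O((mu-x)^2/x),
    # so the flat likelihood valley is resolved far below the scale of the
    # raw Poisson log-likelihood
    delta <- (mu - x) / pmax(x, 1)
    ll <- sum(ifelse(x > 0,
                     ifelse(abs(delta) < 0.5,
                            x * log1p(delta) + (x - mu),
                            x * (log(mu) - log(pmax(x, 1))) + (x - mu)),
                     -mu))
    dr <- logr[pair_a] - logr[pair_b]
    rr <- logr[root_edges]
    pen <- sum(dr^2) + sum((rr - mean(rr))^2)
    val <- -(ll - lambda * pen)
    if (!grad) return(val)

    g_logr <- -(x - mu)
    for (i in seq_along(pair_a)) {
      g_logr[pair_a[i]] <- g_logr[pair_a[i]] + lambda * 2 * dr[i]
      g_logr[pair_b[i]] <- g_logr[pair_b[i]] - lambda * 2 * dr[i]
    }
    g_logr[root_edges] <- g_logr[root_edges] +
      lambda * 2 * (rr - mean(rr))
    g_dur <- x / dur - exp(logr) * n_sites
    g_theta <- numeric(nfree)
    if (nfree > 0)
      g_theta <- -as.numeric(t(ag$J[edge[, 1], , drop = FALSE] -
                                 ag$J[edge[, 2], , drop = FALSE]) %*% g_dur)
    c(g_theta, g_logr)
  }

  init <- function(random = FALSE) {
    theta0 <- rep(0, nfree)
    if (random) theta0 <- stats::rnorm(nfree, 0, 1.5)
    ag <- compute_ages(theta0)
    dur <- pmax(ag$ages[edge[, 1]] - ag$ages[edge[, 2]], 1e-9)
    logr0 <- log(pmax(x, 0.5) / (dur * n_sites))
    if (random) logr0 <- logr0 + stats::rnorm(nedge, 0, 0.5)
    pmin(pmax(c(theta0, logr0), -20), 12)
  }

  list(fn = function(par) eval_all(par, grad = FALSE),
       gr = function(par) eval_all(par, grad = TRUE),
       init = init,
       lower = c(rep(-20, nfree), rep(-25, nedge)),
       upper = c(rep(20, nfree), rep(12, nedge)),
       decode = function(par) {
         ag <- compute_ages(par[seq_len(nfree)])
         list(ages = ag$ages, rates = exp(par[nfree + seq_len(nedge)]))
       })
}

#' Bootstrap node-age distributions over replicate trees
#'
#' Dates every replicate (all sharing one topology) and summarizes each
#' node's age distribution; replicate failures are reported, not silently
#' dropped.
#'
#' @param replicates multiPhylo or list of phylo replicate trees.
#' @param calib A [calibration_set()].
#' @param n_sites Alignment length per replicate.
#' @param lambda Smoothing parameter.
#' @param n_starts,seed,control Passed to [pl_date()]; replicate fits
#'   default to a looser optimizer tolerance than a single definitive fit.
#' @param level Interval coverage (default 0.95 for 2.5/97.5 percentiles).
#' @return List with `summary` (data frame: node clade key, mean, lower,
#'   upper, n_ok), `ages` (replicate x node matrix), `n_failed`.
#' @export
bootstrap_ages <- function(replicates, calib, n_sites, lambda = 1,
                           n_starts = 3L, seed = 1L, level = 0.95,
                           control = list(maxit = 2000, factr = 1e7)) {
  replicates <- as_tree_list(replicates)
  fits <- lapply(seq_along(replicates), function(i)
    tryCatch(pl_date(replicates[[i]], n_sites, calib, lambda,
                     n_starts = n_starts, seed = seed + i,
                     control = control),
             error = function(e) e))
  ok <- !vapply(fits, inherits, TRUE, "error")
  if (sum(ok) < 2) stop("fewer than 2 replicates dated successfully")
  mat <- do.call(rbind, lapply(fits[ok], `[[`, "ages"))
  a <- (1 - level) / 2
  summ <- data.frame(node = colnames(mat),
                     mean = colMeans(mat),
                     lower = apply(mat, 2, stats::quantile, a),
                     upper = apply(mat, 2, stats::quantile, 1 - a),
                     n_ok = sum(ok), stringsAsFactors = FALSE,
                     row.names = NULL)
  list(summary = summ, ages = mat, n_failed = sum(!ok),
       failures = fits[!ok])
}
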