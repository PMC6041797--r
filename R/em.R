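#' Enumerate elementary flux modes of a small network
#'
#' Double-description enumeration of the extreme rays of the flux cone
#' `{v >= 0 : S_split v = 0}` after splitting reversible reactions,
#' using the combinatorial adjacency test to keep only support-minimal
#' combinations. Two-cycle artifacts created by the splitting are removed
#' and the rays are mapped back to net-flux space (forward minus backward).
#' Minimality is re-verified by a pairwise support-inclusion test.
#'
#' Intended for small networks only; enumeration is exponential in general.
#'
#' @param net a [metabolic_network()].
#' @param max_reactions refuse networks with more than this many columns
#'   after reversible splitting (default 60).
#' @param tol zero tolerance for balances.
#' @return object of class `"elementary_modes"`: list with `modes`
#'   (reactions x modes matrix, columns scaled to unit Euclidean norm),
#'   `raw` (integer-scaled copies), `supports` (list of integer index
#'   sets), `network`.
#' @export
enumerate_ems <- function(net, max_reactions = 60, tol = 1e-9) {
  sp <- split_reversible(net)
  Ssp <- sp$network$S
  n <- ncol(Ssp)
  if (n > max_reactions)
    stop("network has ", n, " columns after splitting; enumeration capped at ",
         max_reactions, " reactions")
  R <- diag(n)                      # rows are candidate rays
  A <- R %*% t(Ssp)                 # per-ray metabolite balances
  for (m in seq_len(nrow(Ssp))) {
    a <- A[, m]
    zero <- which(abs(a) <= tol)
    pos <- which(a > tol)
    neg <- which(a < -tol)
    keepR <- R[zero, , drop = FALSE]
    keepA <- A[zero, , drop = FALSE]
    if (length(pos) && length(neg)) {
      supports <- apply(R, 1L, function(r) which(abs(r) > tol),
                        simplify = FALSE)
      newR <- list(); k <- 0L
      for (i in pos) for (j in neg) {
        u <- union(supports[[i]], supports[[j]])
        adjacent <- TRUE
        for (l in seq_len(nrow(R))) {
          if (l == i || l == j) next
          if (all(supports[[l]] %in% u)) { adjacent <- FALSE; break }
        }
        if (!adjacent) next
        r_new <- a[i] * R[j, ] - a[j] * R[i, ]
        r_new <- r_new / max(abs(r_new))
        k <- k + 1L
        newR[[k]] <- r_new
      }
      if (k) {
        newRm <- do.call(rbind, newR)
        keepR <- rbind(keepR, newRm)
        keepA <- rbind(keepA, newRm %*% t(Ssp))
      }
    }
    R <- keepR; A <- keepA
    if (!nrow(R)) break
  }
  ## drop splitting artifacts: rays supported exactly on a forward/backward
  ## pair of the same original reaction
  map <- sp$mapping
  pair_sets <- lapply(which(!is.na(map$backward)), function(r)
    sort(c(map$forward[r], map$backward[r])))
  modes_net <- list(); k <- 0L
  for (i in seq_len(nrow(R))) {
    supp <- sort(which(abs(R[i, ]) > tol))
    if (any(vapply(pair_sets, function(ps) identical(supp, ps), logical(1))))
      next
    v <- recombine_fluxes(R[i, ], map)
    if (max(abs(v)) <= tol) next
    k <- k + 1L
    modes_net[[k]] <- v
  }
  if (!k) stop("network has no elementary mode")
  M <- do.call(cbind, modes_net)
  ## canonical orientation: modes supported only on reversible reactions are
  ## sign-flippable; give them a positive leading entry, then deduplicate
  for (j in seq_len(ncol(M))) {
    supp <- which(abs(M[, j]) > tol)
    if (all(net$reversible[supp])) {
      lead <- supp[1]
      if (M[lead, j] < 0) M[, j] <- -M[, j]
    }
    M[, j] <- M[, j] / max(abs(M[, j]))
  }
  M <- M[, !duplicated(round(t(M), 9)), drop = FALSE]
  ## final pairwise support-minimality check
  supports <- apply(M, 2L, function(v) which(abs(v) > tol), simplify = FALSE)
  minimal <- rep(TRUE, ncol(M))
  for (i in seq_along(supports)) for (j in seq_along(supports)) {
    if (i == j || !minimal[i]) next
    if (length(supports[[j]]) < length(supports[[i]]) &&
        all(supports[[j]] %in% supports[[i]]))
      minimal[i] <- FALSE
  }
  M <- M[, minimal, drop = FALSE]
  supports <- supports[minimal]
  ## integer-scaled copies where coefficients are near-rational
  raw <- apply(M, 2L, function(v) {
    nz <- abs(v)[abs(v) > tol]
    v2 <- v / min(nz)
    if (max(abs(v2 - round(v2))) < 1e-6) round(v2) else v2
  })
  raw <- matrix(raw, nrow = nrow(M))
  unitM <- sweep(M, 2L, sqrt(colSums(M^2)), `/`)
  rownames(unitM) <- rownames(raw) <- net$reaction_ids
  colnames(unitM) <- colnames(raw) <- paste0("EM", seq_len(ncol(unitM)))
  structure(list(modes = unitM, raw = raw, supports = supports,
                 network = net),
            class = "elementary_modes")
}

#' @export
print.elementary_modes <- function(x, ...) {
  cat("Elementary flux modes: ", ncol(x$modes), " mode(s) over ",
      nrow(x$modes), " reactions\n", sep = "")
  cat("  support sizes: ",
      paste(vapply(x$supports, length, integer(1)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Test whether a flux vector is a steady-state mode
#'
#' @param w flux vector.
#' @param net a [metabolic_network()].
#' @param tol tolerance on metabolite imbalance and directionality.
#' @return `TRUE` iff `max |S w| <= tol` and `w >= -tol` on all
#'   irreversible reactions.
#' @export
is_steady_mode <- function(w, net, tol = 1e-8) {
  max(abs(net$S %*% w)) <= tol && all(w[!net$reversible] >= -tol)
}

#' Built-in toy metabolic networks
#'
#' Hard-coded fixtures used throughout the examples and the simulation
#' studies:
#' \describe{
#'   \item{`chain`}{3-reaction linear pathway, 1 elementary mode.}
#'   \item{`branched`}{uptake followed by two alternative export branches,
#'     5 reactions, 2 elementary modes.}
#'   \item{`diamond`}{6 reactions with one reversible shortcut, 3
#'     elementary modes (two through-paths and one internal cycle).}
#'   \item{`mini_ccm`}{a 12-reaction caricature of central carbon
#'     metabolism (glycolysis, TCA-like loop, anaplerosis, fermentation)
#'     with subsystem labels and gene rules; >= 5 elementary modes.}
#'   \item{`sparse_embed`}{40 reactions: one 6-reaction linear pathway
#'     embedded among 17 independent uptake/export pairs; used to study
#'     recovery of a sparse flux mode.}
#' }
#'
#' @param name one of `"chain"`, `"branched"`, `"diamond"`, `"mini_ccm"`,
#'   `"sparse_embed"`.
#' @return a [metabolic_network()].
#' @export
make_toy_network <- function(name = c("chain", "branched", "diamond",
                                      "mini_ccm", "sparse_embed")) {
  name <- match.arg(name)
  tsv <- switch(name,
    chain = c(
      "reaction_id\tequation\treversible\tlb\tub\tsubsystem\tgene_rule",
      "R1\t-> A\tfalse\t\t\t\t",
      "R2\tA -> B\tfalse\t\t\t\t",
      "R3\tB ->\tfalse\t\t\t\t"),
    branched = c(
      "reaction_id\tequation\treversible\tlb\tub\tsubsystem\tgene_rule",
      "R1\t-> A\tfalse\t\t\t\t",
      "R2\tA -> B\tfalse\t\t\t\t",
      "R3\tA -> C\tfalse\t\t\t\t",
      "R4\tB ->\tfalse\t\t\t\t",
      "R5\tC ->\tfalse\t\t\t\t"),
    diamond = c(
      "reaction_id\tequation\treversible\tlb\tub\tsubsystem\tgene_rule",
      "R1\t-> A\tfalse\t\t\t\t",
      "R2\tA -> B\tfalse\t\t\t\t",
      "R3\tA <-> B\ttrue\t\t\t\t",
      "R4\tB -> C\tfalse\t\t\t\t",
      "R5\tC -> D\tfalse\t\t\t\t",
      "R6\tD ->\tfalse\t\t\t\t"),
    mini_ccm = c(
      "reaction_id\tequation\treversible\tlb\tub\tsubsystem\tgene_rule",
      "GLC_up\t-> G6P\tfalse\t\t\tglycolysis\tg_hxk",
      "GLYC\tG6P -> 2 PYR\tfalse\t\t\tglycolysis\tg_pfk and g_fba",
      "PDH\tPYR -> ACO\tfalse\t\t\tlink\tg_pda or g_pdb",
      "CS\tACO + OAA -> AKG\tfalse\t\t\ttca\tg_cit",
      "AKGD\tAKG -> OAA\tfalse\t\t\ttca\tg_kgd and (g_lpd or g_lpd2)",
      "PC\tPYR -> OAA\tfalse\t\t\tana\tg_pyc",
      "PDC\tPYR -> ETH\tfalse\t\t\tferm\tg_pdc",
      "ETH_ex\tETH ->\tfalse\t\t\tferm\t",
      "AKG_ex\tAKG ->\tfalse\t\t\texp\t",
      "OAA_ex\tOAA ->\tfalse\t\t\texp\t",
      "LDH\tPYR <-> LAC\ttrue\t\t\tferm\tg_ldh",
      "LAC_ex\tLAC ->\tfalse\t\t\tferm\t"),
    sparse_embed = {
      chain6 <- c("P1\t-> M1\tfalse\t\t\tpathway\t",
                  "P2\tM1 -> M2\tfalse\t\t\tpathway\t",
                  "P3\tM2 -> M3\tfalse\t\t\tpathway\t",
                  "P4\tM3 -> M4\tfalse\t\t\tpathway\t",
                  "P5\tM4 -> M5\tfalse\t\t\tpathway\t",
                  "P6\tM5 ->\tfalse\t\t\tpathway\t")
      pairs <- unlist(lapply(1:17, function(i) c(
        sprintf("U%d\t-> X%d\tfalse\t\t\tbackground\t", i, i),
        sprintf("E%d\tX%d ->\tfalse\t\t\tbackground\t", i, i))))
      c("reaction_id\tequation\treversible\tlb\tub\tsubsystem\tgene_rule",
        chain6, pairs)
    })
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  writeLines(tsv, path)
  read_network_tsv(path)
}

#' Simulate steady-state flux data as random elementary-mode combinations
#'
#' Each condition activates a fixed set of elementary modes; every sample of
#' that condition is a nonnegative random linear combination of its active
#' modes, with coefficients drawn independently from
#' `Uniform(coeff_range[1], coeff_range[2])` on the unit-norm modes.
#' Gaussian noise proportional to each entry's magnitude is added afterwards
#' via [add_noise()].
#'
#' @param ems an [enumerate_ems()] result.
#' @param active_sets list (one element per condition) of elementary-mode
#'   index vectors active in that condition.
#' @param samples_per_condition samples simulated per condition.
#' @param coeff_range positive coefficient range (default `c(0.5, 2)`).
#' @param noise relative noise level in `[0, 1)` passed to [add_noise()].
#' @param noise_mode see [add_noise()].
#' @param seed integer seed; the simulation is reproducible bit for bit.
#' @return list with `X` (samples x reactions flux matrix, reaction ids as
#'   column names), `active` (per-sample active-mode index sets),
#'   `condition` (per-sample condition index), `truth` (union of all
#'   active mode indices).
#' @export
simulate_flux_data <- function(ems, active_sets, samples_per_condition = 1,
                               coeff_range = c(0.5, 2), noise = 0,
                               noise_mode = c("relative_sd",
                                              "relative_variance"),
                               seed = 1L) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(length(active_sets) >= 1, all(lengths(active_sets) >= 1),
            coeff_range[1] > 0, coeff_range[2] >= coeff_range[1],
            noise >= 0, noise < 1)
  M <- ems$modes
  bad <- setdiff(unlist(active_sets), seq_len(ncol(M)))
  if (length(bad)) stop("active mode index out of range: ",
                        paste(bad, collapse = ", "))
  set.seed(seed)
  n_cond <- length(active_sets)
  N <- n_cond * samples_per_condition
  X <- matrix(0, N, nrow(M))
  active <- vector("list", N)
  condition <- integer(N)
  i <- 0L
  for (cnd in seq_len(n_cond)) {
    act <- sort(unique(active_sets[[cnd]]))
    for (s in seq_len(samples_per_condition)) {
      i <- i + 1L
      coef <- stats::runif(length(act), coeff_range[1], coeff_range[2])
      X[i, ] <- drop(M[, act, drop = FALSE] %*% coef)
      active[[i]] <- act
      condition[i] <- cnd
    }
  }
  if (noise > 0) X <- add_noise(X, noise, seed = seed + 1L, mode = noise_mode)
  dimnames(X) <- list(paste0("s", seq_len(N)), rownames(M))
  list(X = X, active = active, condition = condition,
       truth = sort(unique(unlist(active_sets))))
}

#' Add magnitude-proportional Gaussian noise
#'
#' Entry `x` becomes `x + e` with `e ~ Normal(0, sd = level * |x|)`
#' (`mode = "relative_sd"`, the default) or
#' `e ~ Normal(0, var = level * |x|)` (`mode = "relative_variance"`).
#' Zero entries are left unchanged in both modes.
#'
#' @param X numeric matrix.
#' @param level nonnegative noise level.
#' @param seed optional integer seed.
#' @param mode noise law, see above.
#' @return matrix of the same shape.
#' @export
add_noise <- function(X, level, seed = NULL,
                      mode = c("relative_sd", "relative_variance")) {
  mode <- match.arg(mode)
  stopifnot(level >= 0)
  if (level == 0) return(X)
  if (!is.null(seed)) set.seed(seed)
  sd <- if (mode == "relative_sd") level * abs(X) else sqrt(level * abs(X))
  X + matrix(stats::rnorm(length(X), 0, c(sd)), nrow(X), ncol(X))
}
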