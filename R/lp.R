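## Dense two-phase primal simplex for small linear programs:
##   max c'x  s.t.  Aeq x = beq,  l <= x <= u
## with possibly infinite bounds. Variables are shifted/split to standard
## form (x >= 0), finite upper bounds become slack rows, and Bland's rule
## prevents cycling. Written for the small FBA problems in scope; no LP
## package is part of the package's dependency set.
simplex_tableau <- function(A, b, cmin, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  ## phase 1: artificials
  Tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  obj <- c(rep(0, n), rep(1, m))
  run <- function(obj, phase1) {
    repeat {
      ## reduced costs
      cb <- obj[basis]
      z <- drop(cb %*% Tab[, seq_len(ncol(Tab) - 1L), drop = FALSE])
      red <- obj - z
      if (phase1) red[basis] <- 0
      enter_cand <- which(red < -tol)
      if (phase1) enter_cand <- setdiff(enter_cand, integer(0))
      if (!length(enter_cand)) return("optimal")
      e <- min(enter_cand)                    # Bland
      col <- Tab[, e]
      rhs <- Tab[, ncol(Tab)]
      pos <- which(col > tol)
      if (!length(pos)) return("unbounded")
      ratios <- rhs[pos] / col[pos]
      r <- pos[which(ratios == min(ratios))]
      r <- r[which.min(basis[r])]             # Bland on leaving variable
      piv <- Tab[r, e]
      Tab[r, ] <<- Tab[r, ] / piv
      for (i in seq_len(m)) if (i != r && abs(Tab[i, e]) > 0)
        Tab[i, ] <<- Tab[i, ] - Tab[i, e] * Tab[r, ]
      basis[r] <<- e
    }
  }
  st <- run(obj, phase1 = TRUE)
  phase1_obj <- sum(obj[basis] * Tab[, ncol(Tab)])
  if (st != "optimal" || phase1_obj > 1e-7) return(list(status = "infeasible"))
  ## drive artificials out of the basis where possible
  for (r in which(basis > n)) {
    piv_cols <- which(abs(Tab[r, seq_len(n)]) > tol)
    if (length(piv_cols)) {
      e <- piv_cols[1]
      piv <- Tab[r, e]
      Tab[r, ] <- Tab[r, ] / piv
      for (i in seq_len(m)) if (i != r && abs(Tab[i, e]) > 0)
        Tab[i, ] <- Tab[i, ] - Tab[i, e] * Tab[r, ]
      basis[r] <- e
    }
  }
  ## phase 2 on original columns only (artificial columns frozen)
  obj2 <- c(cmin, rep(1e30, m))
  st <- run(obj2, phase1 = FALSE)
  if (st == "unbounded") return(list(status = "unbounded"))
  x <- rep(0, n)
  inb <- basis <= n
  x[basis[inb]] <- Tab[inb, ncol(Tab)]
  list(status = "optimal", x = x, value = -sum(cmin * x) * -1)
}

lp_solve <- function(cmax, Aeq, beq, lb, ub) {
  n <- length(cmax)
  ## shift/split to x >= 0
  map <- vector("list", n)
  cols <- list(); shift <- numeric(n); k <- 0L
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) {
      k <- k + 1L; map[[j]] <- list(type = "shift_lo", idx = k)
    } else if (is.finite(ub[j])) {
      k <- k + 1L; map[[j]] <- list(type = "shift_hi", idx = k)
    } else {
      map[[j]] <- list(type = "free", idx = c(k + 1L, k + 2L)); k <- k + 2L
    }
  }
  nn <- k
  A1 <- matrix(0, nrow(Aeq), nn)
  b1 <- beq
  cm <- rep(0, nn)
  ub_rows <- list()
  for (j in seq_len(n)) {
    mp <- map[[j]]
    if (mp$type == "shift_lo") {
      A1[, mp$idx] <- Aeq[, j]
      b1 <- b1 - Aeq[, j] * lb[j]
      cm[mp$idx] <- cmax[j]
      if (is.finite(ub[j]))
        ub_rows[[length(ub_rows) + 1L]] <- c(mp$idx, ub[j] - lb[j])
    } else if (mp$type == "shift_hi") {
      A1[, mp$idx] <- -Aeq[, j]               # x_j = ub - x'
      b1 <- b1 - Aeq[, j] * ub[j]
      cm[mp$idx] <- -cmax[j]
    } else {
      A1[, mp$idx[1]] <- Aeq[, j]
      A1[, mp$idx[2]] <- -Aeq[, j]
      cm[mp$idx] <- c(cmax[j], -cmax[j])
    }
  }
  ## finite upper bounds as equality rows with slack
  if (length(ub_rows)) {
    ns <- length(ub_rows)
    A2 <- matrix(0, ns, nn + ns)
    b2 <- numeric(ns)
    for (i in seq_along(ub_rows)) {
      A2[i, ub_rows[[i]][1]] <- 1
      A2[i, nn + i] <- 1
      b2[i] <- ub_rows[[i]][2]
    }
    A1 <- rbind(cbind(A1, matrix(0, nrow(A1), ns)), A2)
    b1 <- c(b1, b2)
    cm <- c(cm, rep(0, ns))
  }
  res <- simplex_tableau(A1, b1, -cm)         # maximize -> minimize -c
  if (res$status != "optimal") return(list(status = res$status))
  xs <- res$x
  x <- numeric(n)
  for (j in seq_len(n)) {
    mp <- map[[j]]
    x[j] <- switch(mp$type,
      shift_lo = xs[mp$idx] + lb[j],
      shift_hi = ub[j] - xs[mp$idx],
      free = xs[mp$idx[1]] - xs[mp$idx[2]])
  }
  list(status = "optimal", x = x, value = sum(cmax * x))
}
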