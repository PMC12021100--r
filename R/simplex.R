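# Deterministic two-phase simplex for small bounded LPs:
#   maximize c'v  s.t.  Aeq v = beq, lb <= v <= ub
# Bland's rule throughout, so the solve is exact-arithmetic-stable and
# reproducible. Intended for toy stoichiometric models (tens of
# variables); not a large-scale solver.

.lpSolve <- function(cc, Aeq, beq, lb, ub, tol = 1e-9) {
  n <- length(cc)
  m <- nrow(Aeq)
  rng <- ub - lb
  # shift x = v - lb >= 0; add slack s for x + s = ub - lb
  b1 <- as.numeric(beq - Aeq %*% lb)
  A <- rbind(cbind(Aeq, matrix(0, m, n)),
             cbind(diag(n), diag(n)))
  b <- c(b1, rng)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  M <- nrow(A); N <- ncol(A)
  # phase 1: artificial basis
  Tab <- cbind(A, diag(M), b)
  basis <- N + seq_len(M)
  obj <- c(rep(0, N), rep(1, M)) # minimize sum of artificials
  res <- .simplexIter(Tab, basis, obj, N + M, tol)
  if (res$value > 1e-7) return(list(status = "infeasible"))
  Tab <- res$Tab; basis <- res$basis
  # drive remaining artificials out of the basis
  for (r in which(basis > N)) {
    piv <- which(abs(Tab[r, seq_len(N)]) > tol)[1L]
    if (is.na(piv)) next # redundant row
    Tab[r, ] <- Tab[r, ] / Tab[r, piv]
    for (i in seq_len(nrow(Tab))[-r])
      Tab[i, ] <- Tab[i, ] - Tab[i, piv] * Tab[r, ]
    basis[r] <- piv
  }
  keep <- basis <= N
  Tab <- Tab[keep, c(seq_len(N), ncol(Tab)), drop = FALSE]
  basis <- basis[keep]
  # phase 2: minimize -c'x (maximize c'v)
  obj2 <- c(-cc, rep(0, N - n))
  res <- .simplexIter(Tab, basis, obj2, N, tol)
  if (identical(res$status, "unbounded"))
    return(list(status = "unbounded"))
  x <- numeric(N)
  x[res$basis] <- res$Tab[, ncol(res$Tab)]
  v <- x[seq_len(n)] + lb
  list(status = "optimal", v = v, objective = sum(cc * v))
}

# tableau simplex iterations with Bland's rule; obj over columns 1..N
.simplexIter <- function(Tab, basis, obj, N, tol) {
  repeat {
    M <- nrow(Tab)
    cb <- obj[basis]
    red <- obj[seq_len(N)] -
      as.numeric(crossprod(cb, Tab[, seq_len(N), drop = FALSE]))
    enter <- which(red < -tol)
    if (!length(enter)) {
      value <- sum(cb * Tab[, ncol(Tab)])
      return(list(Tab = Tab, basis = basis, value = value,
                  status = "optimal"))
    }
    j <- enter[1L] # Bland: smallest index
    col <- Tab[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded", Tab = Tab,
                                  basis = basis))
    ratio <- Tab[pos, ncol(Tab)] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    r <- cand[which.min(basis[cand])] # Bland on leaving variable
    Tab[r, ] <- Tab[r, ] / Tab[r, j]
    for (i in seq_len(M)[-r])
      Tab[i, ] <- Tab[i, ] - Tab[i, j] * Tab[r, ]
    basis[r] <- j
  }
}
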