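#' @title Internal linear-programming core
#' @description A small, deterministic two-phase dense simplex with Bland's
#' rule. The flux LPs solved here are tiny (tens of variables) but routinely
#' degenerate (equality-dominated stoichiometric systems with ties at
#' vertices), which defeats the recommended-package simplex implementation;
#' Bland's rule guarantees termination and the fixed pivoting order makes the
#' returned vertex reproducible across platforms.
#' @name lp-internal
#' @keywords internal
NULL

## minimize c'x subject to A1 x <= b1, A2 x >= b2, A3 x = b3, x >= 0
## returns list(status, x, value); status in optimal|infeasible|unbounded
lp_dense <- function(c_obj, A1 = NULL, b1 = NULL, A2 = NULL, b2 = NULL,
                     A3 = NULL, b3 = NULL, maxi = FALSE,
                     tol = 1e-9, max_iter = 20000L) {
  n <- length(c_obj)
  blocks <- list(list(A1, b1, "le"), list(A2, b2, "ge"), list(A3, b3, "eq"))
  A <- NULL; h <- numeric(0); type <- character(0)
  for (bl in blocks) {
    if (is.null(bl[[1]])) next
    Am <- matrix(bl[[1]], ncol = n)
    A <- rbind(A, Am); h <- c(h, bl[[2]]); type <- c(type, rep(bl[[3]], nrow(Am)))
  }
  m <- length(h)
  for (i in seq_len(m)) if (h[i] < 0) {
    A[i, ] <- -A[i, ]; h[i] <- -h[i]
    type[i] <- switch(type[i], le = "ge", ge = "le", eq = "eq")
  }
  nslack <- sum(type != "eq")
  nart <- sum(type != "le")
  N <- n + nslack + nart
  Tb <- matrix(0, m, N); Tb[, seq_len(n)] <- A
  basis <- integer(m); js <- n; ja <- n + nslack
  for (i in seq_len(m)) {
    if (type[i] == "le") { js <- js + 1L; Tb[i, js] <- 1; basis[i] <- js }
    else if (type[i] == "ge") { js <- js + 1L; Tb[i, js] <- -1; ja <- ja + 1L; Tb[i, ja] <- 1; basis[i] <- ja }
    else { ja <- ja + 1L; Tb[i, ja] <- 1; basis[i] <- ja }
  }
  run <- function(cost, basis, Tb, h, allowed) {
    for (it in seq_len(max_iter)) {
      red <- cost - as.vector(crossprod(Tb, cost[basis]))
      red[basis] <- 0
      enter <- 0L
      for (j in allowed) if (red[j] < -tol) { enter <- j; break }  # Bland
      if (enter == 0L) return(list(status = "optimal", basis = basis, Tb = Tb, h = h))
      col <- Tb[, enter]
      ratio <- ifelse(col > tol, h / col, Inf)
      if (all(!is.finite(ratio))) return(list(status = "unbounded"))
      pr <- which(ratio == min(ratio))
      if (length(pr) > 1L) pr <- pr[which.min(basis[pr])]   # Bland tie-break
      pv <- Tb[pr, enter]
      Tb[pr, ] <- Tb[pr, ] / pv; h[pr] <- h[pr] / pv
      upd <- setdiff(seq_len(m), pr)
      f <- Tb[upd, enter]
      Tb[upd, ] <- Tb[upd, ] - outer(f, Tb[pr, ])
      h[upd] <- h[upd] - f * h[pr]
      basis[pr] <- enter
    }
    list(status = "maxiter")
  }
  if (nart > 0L) {
    r <- run(c(rep(0, n + nslack), rep(1, nart)), basis, Tb, h, seq_len(N))
    if (!identical(r$status, "optimal")) return(list(status = "infeasible"))
    basis <- r$basis; Tb <- r$Tb; h <- r$h
    if (sum(h[basis > n + nslack]) > 1e-7) return(list(status = "infeasible"))
    for (i in which(basis > n + nslack)) {   # drive artificials out where possible
      j <- which(abs(Tb[i, seq_len(n + nslack)]) > tol)[1]
      if (!is.na(j)) {
        pv <- Tb[i, j]; Tb[i, ] <- Tb[i, ] / pv; h[i] <- h[i] / pv
        upd <- setdiff(seq_len(m), i); f <- Tb[upd, j]
        Tb[upd, ] <- Tb[upd, ] - outer(f, Tb[i, ]); h[upd] <- h[upd] - f * h[i]
        basis[i] <- j
      }
    }
  }
  obj <- if (maxi) -c_obj else c_obj
  r <- run(c(obj, rep(0, nslack + nart)), basis, Tb, h, seq_len(n + nslack))
  if (identical(r$status, "unbounded")) return(list(status = "unbounded"))
  if (!identical(r$status, "optimal")) return(list(status = r$status))
  x <- numeric(N); x[r$basis] <- r$h
  sol <- x[seq_len(n)]
  list(status = "optimal", x = sol, value = sum(c_obj * sol))
}
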