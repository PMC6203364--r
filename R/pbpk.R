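#' Two-compartment pharmacokinetic system
#'
#' Defines the physiologically based pharmacokinetic (PBPK) model used to
#' motivate the boundary-condition decay regimes of the drug solver: a
#' vascularized compartment with concentration `C1` exchanging drug with an
#' avascular compartment `C2`,
#' \deqn{dC_1/dt = k_{21} (V_2/V_1) C_2 - (k_{12} + k_{10}) C_1 + S(t)/V_1}
#' \deqn{dC_2/dt = k_{12} (V_1/V_2) C_1 - k_{21} C_2}
#' where `k21`, `k12` are exchange rate constants, `k10` the elimination rate
#' into other organs, `V1`, `V2` the compartment volumes and `S(t)` a dosage
#' source. Defaults are the CPT-11 parameter set with an impulse dose encoded
#' as the initial condition `C1 = 1`, `C2 = 0.2` ug/ml.
#'
#' @param k21,k12,k10 transport rate constants (day^-1), strictly positive
#'   (`k10` may be zero to seal the system).
#' @param V1,V2 compartment volumes (ml), strictly positive.
#' @param C1,C2 initial concentrations (ug/ml), non-negative.
#' @param S dosage source (ug/day): a function of time in days, or a single
#'   number for a constant infusion.
#' @return An object of class `pbpk_system`.
#' @examples
#' sys <- pbpk_system()
#' pbpk_derivatives(sys, 0)
#' @export
pbpk_system <- function(k21 = 1.48, k12 = 0.276, k10 = 13.27,
                        V1 = 4.85e3, V2 = 8.0e3,
                        C1 = 1.0, C2 = 0.2, S = 0) {
  if (!all(is.finite(c(k21, k12, k10))) || k21 <= 0 || k12 <= 0 || k10 < 0)
    stop("rate constants must be positive (k10 may be 0)")
  if (!all(is.finite(c(V1, V2))) || V1 <= 0 || V2 <= 0)
    stop("compartment volumes must be strictly positive")
  if (C1 < 0 || C2 < 0)
    stop("initial concentrations must be non-negative")
  if (is.numeric(S)) {
    Sval <- S
    S <- function(t) rep_len(Sval, length(t))
  }
  structure(list(k21 = k21, k12 = k12, k10 = k10, V1 = V1, V2 = V2,
                 C1 = C1, C2 = C2, S = S),
            class = "pbpk_system")
}

#' @export
print.pbpk_system <- function(x, ...) {
  cat("Two-compartment PBPK system\n")
  cat(sprintf("  k21 = %g, k12 = %g, k10 = %g day^-1\n", x$k21, x$k12, x$k10))
  cat(sprintf("  V1 = %g ml, V2 = %g ml\n", x$V1, x$V2))
  cat(sprintf("  C1(0) = %g, C2(0) = %g ug/ml\n", x$C1, x$C2))
  invisible(x)
}

#' PBPK right-hand side
#'
#' Evaluates the derivatives of the two-compartment model at time `t`.
#'
#' @param sys a [pbpk_system()].
#' @param t time (days).
#' @param C1,C2 concentrations at which to evaluate (default: the system's
#'   initial values).
#' @return Named numeric vector `c(dC1, dC2)` in ug ml^-1 day^-1.
#' @export
pbpk_derivatives <- function(sys, t, C1 = sys$C1, C2 = sys$C2) {
  stopifnot(inherits(sys, "pbpk_system"))
  dC1 <- sys$k21 * (sys$V2 / sys$V1) * C2 - (sys$k12 + sys$k10) * C1 +
    sys$S(t) / sys$V1
  dC2 <- sys$k12 * (sys$V1 / sys$V2) * C1 - sys$k21 * C2
  c(dC1 = dC1, dC2 = dC2)
}

# system matrix of the linear part
.pbpk_matrix <- function(sys) {
  matrix(c(-(sys$k12 + sys$k10), sys$k21 * sys$V2 / sys$V1,
           sys$k12 * sys$V1 / sys$V2, -sys$k21),
         nrow = 2, byrow = TRUE)
}

#' Integrate the PBPK system
#'
#' Fixed-step classical Runge-Kutta (RK4) integration. The step must resolve
#' the fastest rate (elimination `k10` dominates); a step too large for the
#' explicit scheme is refused with the stable bound reported.
#'
#' @param sys a [pbpk_system()].
#' @param t_end end time (days).
#' @param dt time step (days); default 1e-3 resolves `k10` ~ 13 day^-1.
#' @return A data frame with columns `t`, `C1`, `C2`.
#' @examples
#' traj <- pbpk_solve(pbpk_system(), t_end = 1)
#' head(traj)
#' @export
pbpk_solve <- function(sys, t_end, dt = 1e-3) {
  stopifnot(inherits(sys, "pbpk_system"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.finite(t_end) || t_end < 0) stop("t_end must be >= 0")
  A <- .pbpk_matrix(sys)
  lam <- max(abs(eigen(A, only.values = TRUE)$values))
  dt_max <- 2.78 / lam  # RK4 real-axis stability limit
  if (dt > dt_max)
    stop(sprintf("dt = %g day unstable for this system; need dt <= %.4g day",
                 dt, dt_max))
  n <- ceiling(t_end / dt)
  if (n == 0) {
    return(data.frame(t = 0, C1 = sys$C1, C2 = sys$C2))
  }
  h <- t_end / n
  S <- sys$S
  f <- function(t, y) c(A[1, 1] * y[1] + A[1, 2] * y[2] + S(t) / sys$V1,
                        A[2, 1] * y[1] + A[2, 2] * y[2])
  out <- matrix(NA_real_, n + 1, 3)
  y <- c(sys$C1, sys$C2)
  out[1, ] <- c(0, y)
  t <- 0
  for (i in seq_len(n)) {
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    out[i + 1, ] <- c(t, y)
  }
  data.frame(t = out[, 1], C1 = out[, 2], C2 = out[, 3])
}

#' Write a PBPK trajectory to CSV
#'
#' @param traj data frame from [pbpk_solve()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_pbpk_csv <- function(traj, path) {
  write.csv(traj, path, row.names = FALSE)
  invisible(path)
}
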