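#' Segment mechanical properties
#'
#' Properties of one vessel segment for the 1D flow model. The wall is
#' elastic with the nonlinear pressure-area tube law
#' `p = p_ext + beta (sqrt(A) - sqrt(A0))`; the linearised pulse-wave
#' speed at the reference area is `c0 = sqrt(beta sqrt(A0) / (2 rho))`.
#'
#' @param A0_m2 Reference cross-sectional area (m^2), > 0.
#' @param beta_Pa_m Wall stiffness coefficient (Pa/m), > 0.
#' @param length_m Segment length (m), > 0.
#' @param rho Blood density (kg/m^3), default 1050.
#' @param mu Dynamic viscosity (Pa s), default 3.5e-3.
#' @param n_grid Number of finite-volume cells (>= 3).
#' @return A `segment_properties` object.
#' @export
segment_properties <- function(A0_m2, beta_Pa_m, length_m, rho = 1050,
                               mu = 3.5e-3, n_grid = 32L) {
  stopifnot(A0_m2 > 0, beta_Pa_m > 0, length_m > 0, rho > 0, mu > 0,
            n_grid >= 3)
  structure(list(A0 = A0_m2, beta = beta_Pa_m, length = length_m,
                 rho = rho, mu = mu, n_grid = as.integer(n_grid)),
            class = "segment_properties")
}

#' Lumped-parameter vascular bed (RCR Windkessel)
#'
#' Proximal resistance, compliance, distal resistance: the bed impedance
#' connecting the arterial terminal to the venous side of a
#' microcirculation. Dynamics of the compliance pressure `p_c`:
#' `C dp_c/dt = (p_art - p_c)/R_prox - (p_c - p_ven)/R_dist`.
#'
#' @param R_prox,R_dist Resistances (Pa s / m^3), > 0.
#' @param C Compliance (m^3 / Pa), > 0.
#' @param region_term Optional anatomy term of the supplied region.
#' @return A `lumped_bed` object.
#' @export
lumped_bed <- function(R_prox, R_dist, C, region_term = NULL) {
  stopifnot(R_prox > 0, R_dist > 0, C > 0)
  structure(list(R_prox = R_prox, R_dist = R_dist, C = C,
                 region_term = if (is.null(region_term)) NULL
                               else term_id(region_term)),
            class = "lumped_bed")
}

#' Advance an RCR bed by one time step (exact linear update)
#'
#' The compliance pressure obeys a linear constant-coefficient ODE over a
#' step with frozen boundary pressures; the update is its closed-form
#' exponential solution, so the relaxation time constant
#' `tau = C R_prox R_dist / (R_prox + R_dist)` (for fixed `p_art`,
#' `p_ven`) is reproduced exactly.
#'
#' @param bed A [lumped_bed()].
#' @param p_art,p_ven Arterial / venous boundary pressures (Pa).
#' @param state List with `p_c` (compliance pressure, Pa).
#' @param dt Time step (s), > 0.
#' @return List: `Q` (through-flow `(p_art - p_c)/R_prox` at the end of
#'   the step) and `state` (updated).
#' @export
bed_update <- function(bed, p_art, p_ven, state = list(p_c = 0), dt) {
  stopifnot(dt > 0)
  a <- (1 / bed$R_prox + 1 / bed$R_dist) / bed$C
  b <- (p_art / bed$R_prox + p_ven / bed$R_dist) / bed$C
  p_inf <- b / a
  p_c <- p_inf + (state$p_c - p_inf) * exp(-a * dt)
  list(Q = (p_art - p_c) / bed$R_prox, state = list(p_c = p_c))
}

#' Cardiac inflow waveform
#'
#' Periodic volumetric inflow applied at the network root throughout the
#' cardiac cycle.
#'
#' @param fun Function of time (s) returning inflow (m^3/s), or a single
#'   number for steady inflow.
#' @param period_s Cycle period (s), > 0.
#' @return A `cardiac_input` object.
#' @export
cardiac_input <- function(fun, period_s = 0.8) {
  stopifnot(period_s > 0)
  if (is.numeric(fun)) {
    q0 <- fun
    fun <- function(t) rep(q0, length(t))
  }
  structure(list(fun = fun, period = period_s), class = "cardiac_input")
}

#' @rdname cardiac_input
#' @param Q_mean,Q_amp Mean and pulse amplitude (m^3/s) of a raised-sine
#'   waveform `Q_mean + Q_amp * sin(2 pi t / period)`.
#' @export
sine_inflow <- function(Q_mean, Q_amp, period_s = 0.8) {
  cardiac_input(function(t) Q_mean + Q_amp * sin(2 * pi * t / period_s),
                period_s)
}

#' Assemble a 1D flow model
#'
#' Segments connect at named junction nodes in the direction of flow.
#' Beds connect an arterial terminal node to a venous start node (or
#' drain to the fixed venous pressure when `to` is `NA`). Any node with
#' inflowing segments, no outflowing segments and no bed is a fixed
#' pressure outlet at `p_out`.
#'
#' @param segments Named list; each element a list with `from`, `to`
#'   (node ids) and `props` (a [segment_properties()]).
#' @param beds List of lists with `bed` (a [lumped_bed()]), `from`
#'   (arterial terminal node) and `to` (venous start node or `NA`).
#' @param inlet Node id where the cardiac inflow enters.
#' @param p_out Fixed outlet pressure (Pa), default 0 (relative).
#' @param p_ext External (tissue) pressure (Pa), default 0.
#' @return A `flow_model` object.
#' @export
flow_model <- function(segments, beds = list(), inlet, p_out = 0, p_ext = 0) {
  stopifnot(length(segments) > 0)
  if (is.null(names(segments)) || any(!nzchar(names(segments))))
    stop("segments must be a named list", call. = FALSE)
  structure(list(segments = segments, beds = beds, inlet = inlet,
                 p_out = p_out, p_ext = p_ext),
            class = "flow_model")
}

#' @export
print.flow_model <- function(x, ...) {
  cat(sprintf("flow model: %d segments, %d beds, inlet at node %s\n",
              length(x$segments), length(x$beds), x$inlet))
  invisible(x)
}

## ---- internal solver machinery ------------------------------------------

## tube law and helpers (per segment properties pr)
.p_of_A <- function(A, pr, p_ext) p_ext + pr$beta * (sqrt(A) - sqrt(pr$A0))
.A_of_p <- function(p, pr, p_ext) ((p - p_ext) / pr$beta + sqrt(pr$A0))^2
.c_of_A <- function(A, pr) sqrt(pr$beta * sqrt(A) / (2 * pr$rho))

.flux <- function(A, Q, pr) {
  list(F1 = Q, F2 = Q^2 / A + pr$beta * A^1.5 / (3 * pr$rho))
}

## damped Newton with numeric Jacobian for small boundary systems;
## `scale` gives the typical magnitude of each unknown so difference
## steps stay meaningful near zero (velocities start at rest)
.newton <- function(fn, x0, scale = pmax(abs(x0), 1), tol = 1e-12,
                    maxit = 60L) {
  x <- x0
  f <- fn(x)
  for (it in seq_len(maxit)) {
    if (max(abs(f)) < tol) break
    n <- length(x)
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- max(abs(x[j]), scale[j]) * 1e-7
      xp <- x; xp[j] <- xp[j] + h
      J[, j] <- (fn(xp) - f) / h
    }
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      xn <- x - lam * step
      fn2 <- fn(xn)
      if (all(is.finite(fn2)) && (max(abs(fn2)) < max(abs(f)) || lam < 1e-4)) {
        x <- xn; f <- fn2; break
      }
      lam <- lam / 2
    }
  }
  list(x = x, resid = max(abs(f)))
}

#' Solve pulsatile 1D flow over a network
#'
#' Integrates the 1D mass and momentum equations
#' (`dA/dt + dQ/dx = 0`;
#' `du/dt + u du/dx = -(1/rho) dp/dx - 8 pi mu u / (rho A)`) with the
#' `beta` tube law on every segment, by a conservative two-step
#' Lax-Wendroff (Richtmyer) finite-volume scheme with semi-implicit
#' Poiseuille friction (the discrete steady state balances the flux
#' divergence against friction exactly). Boundary and junction states
#' are solved from characteristic compatibility (Riemann invariants
#' `u +/- 4c`) with continuity of static pressure and exact mass balance
#' at junctions; terminal beds follow RCR dynamics. Interface fluxes are
#' reused for the mass ledger, so the global balance holds to round-off.
#'
#' @param model A [flow_model()].
#' @param inflow A [cardiac_input()].
#' @param t_end Simulated time (s).
#' @param dt Time step (s); `NULL` chooses `cfl * min(dx)/max(c0)` and
#'   the step auto-reduces (with one warning) if the CFL bound tightens.
#' @param cfl CFL safety factor, default 0.8.
#' @param save_every Save state every this many steps.
#' @return A `flow_state`: per segment matrices `A`, `Q`, `p`, `u`
#'   (cells x saved times), saved `t`, bed pressure traces, the model,
#'   and a mass `audit` (inflow, outflow, tube and bed storage, m^3).
#' @export
solve_flow <- function(model, inflow, t_end, dt = NULL, cfl = 0.8,
                       save_every = 1L) {
  segs <- model$segments
  ids <- names(segs)
  p_ext <- model$p_ext
  ## per-segment discretisation
  S <- lapply(segs, function(s) {
    pr <- s$props
    N <- pr$n_grid
    list(pr = pr, N = N, dx = pr$length / N,
         A = rep(pr$A0, N), Q = rep(0, N))
  })
  names(S) <- ids
  ## node bookkeeping
  nodes <- unique(c(vapply(segs, `[[`, character(1), "from"),
                    vapply(segs, `[[`, character(1), "to")))
  ins <- lapply(nodes, function(n) ids[vapply(segs, function(s) s$to == n, logical(1))])
  outs <- lapply(nodes, function(n) ids[vapply(segs, function(s) s$from == n, logical(1))])
  names(ins) <- names(outs) <- nodes
  bed_from <- vapply(model$beds, function(b) b$from, character(1))
  bed_to <- vapply(model$beds, function(b)
    if (is.null(b$to) || is.na(b$to)) NA_character_ else b$to, character(1))
  node_type <- vapply(nodes, function(n) {
    if (identical(n, model$inlet)) "inlet"
    else if (n %in% bed_from) "bed_art"
    else if (n %in% bed_to) "bed_ven"
    else if (length(ins[[n]]) > 0 && length(outs[[n]]) > 0) "junction"
    else "outlet"
  }, character(1))

  if (is.null(dt)) {
    c0 <- vapply(S, function(s) .c_of_A(s$pr$A0, s$pr), numeric(1))
    dxs <- vapply(S, function(s) s$dx, numeric(1))
    dt <- cfl * min(dxs / c0)
  }
  nt <- ceiling(t_end / dt)
  saved <- unique(c(seq(0, nt, by = save_every), nt))
  t_saved <- saved * dt
  out <- lapply(S, function(s)
    list(A = matrix(NA_real_, s$N, length(saved)),
         Q = matrix(NA_real_, s$N, length(saved))))
  bed_state <- lapply(model$beds, function(b) list(p_c = 0))
  bed_trace <- matrix(NA_real_, length(model$beds), length(saved))
  audit <- list(inflow = 0, outflow = 0,
                tube0 = sum(vapply(S, function(s) sum(s$A) * s$dx, numeric(1))),
                bed0 = 0)
  warned_cfl <- FALSE
  ksave <- 1L
  snap <- function() {
    for (id in ids) {
      out[[id]]$A[, ksave] <<- S[[id]]$A
      out[[id]]$Q[, ksave] <<- S[[id]]$Q
    }
    if (length(model$beds))
      bed_trace[, ksave] <<- vapply(bed_state, `[[`, numeric(1), "p_c")
    ksave <<- ksave + 1L
  }
  snap()

  ## persistent warm starts for boundary solves
  warm <- new.env(parent = emptyenv())

  step_once <- function(t_now, h) {
    ## characteristic info at segment ends (time n)
    W1 <- W2 <- Aend <- Astart <- numeric(length(ids))
    names(W1) <- names(W2) <- names(Aend) <- names(Astart) <- ids
    for (id in ids) {
      s <- S[[id]]
      w1 <- s$Q / s$A + 4 * .c_of_A(s$A, s$pr)
      w2 <- s$Q / s$A - 4 * .c_of_A(s$A, s$pr)
      ## linear extrapolation from the last two cell centres to the face
      W1[id] <- if (s$N >= 2) w1[s$N] + 0.5 * (w1[s$N] - w1[s$N - 1])
                else w1[s$N]
      W2[id] <- if (s$N >= 2) w2[1] - 0.5 * (w2[2] - w2[1]) else w2[1]
      Aend[id] <- s$A[s$N]; Astart[id] <- s$A[1]
    }
    ## boundary states per segment end
    bF1 <- bF2 <- eF1 <- eF2 <- numeric(length(ids)) # start/end fluxes
    names(bF1) <- names(bF2) <- names(eF1) <- names(eF2) <- ids
    Q_in_net <- 0; Q_out_net <- 0
    bed_Qin <- numeric(length(model$beds))
    bed_Qout <- numeric(length(model$beds))

    solve_node <- function(n) {
      typ <- node_type[[n]]
      iseg <- ins[[n]]; oseg <- outs[[n]]
      if (typ == "inlet") {
        id <- oseg[1]
        pr <- S[[id]]$pr
        Qt <- inflow$fun(t_now)
        key <- paste0("n_", n)
        x0 <- if (!is.null(warm[[key]])) warm[[key]] else c(Astart[id], 0)
        sc_u <- .c_of_A(pr$A0, pr); sc_q <- pr$A0 * sc_u
        r <- .newton(function(x) {
          A <- x[1]; u <- x[2]
          c((u - 4 * .c_of_A(A, pr) - W2[id]) / sc_u,
            (A * u - Qt) / sc_q)
        }, x0, scale = c(pr$A0, sc_u))
        warm[[key]] <- r$x
        A <- r$x[1]; u <- r$x[2]
        f <- .flux(A, A * u, pr)
        bF1[id] <<- f$F1; bF2[id] <<- f$F2
        Q_in_net <<- Q_in_net + A * u
      } else if (typ == "outlet") {
        for (id in iseg) {
          pr <- S[[id]]$pr
          A <- .A_of_p(model$p_out, pr, p_ext)
          u <- W1[id] - 4 * .c_of_A(A, pr)
          f <- .flux(A, A * u, pr)
          eF1[id] <<- f$F1; eF2[id] <<- f$F2
          Q_out_net <<- Q_out_net + A * u
        }
      } else if (typ == "bed_art") {
        bidx <- which(bed_from == n)
        for (bi in bidx) {
          id <- iseg[1]
          pr <- S[[id]]$pr
          bed <- model$beds[[bi]]$bed
          p_c <- bed_state[[bi]]$p_c
          key <- paste0("n_", n)
          x0 <- if (!is.null(warm[[key]])) warm[[key]] else c(Aend[id], 0)
          sc_u <- .c_of_A(pr$A0, pr); sc_q <- pr$A0 * sc_u
          r <- .newton(function(x) {
            A <- x[1]; u <- x[2]
            c((u + 4 * .c_of_A(A, pr) - W1[id]) / sc_u,
              (A * u - (.p_of_A(A, pr, p_ext) - p_c) / bed$R_prox) / sc_q)
          }, x0, scale = c(pr$A0, sc_u))
          warm[[key]] <- r$x
          A <- r$x[1]; u <- r$x[2]
          f <- .flux(A, A * u, pr)
          eF1[id] <<- f$F1; eF2[id] <<- f$F2
          bed_Qin[bi] <<- A * u
        }
      } else if (typ == "bed_ven") {
        bidx <- which(bed_to == n)
        for (bi in bidx) {
          id <- oseg[1]
          pr <- S[[id]]$pr
          bed <- model$beds[[bi]]$bed
          p_c <- bed_state[[bi]]$p_c
          key <- paste0("n_", n)
          x0 <- if (!is.null(warm[[key]])) warm[[key]] else c(Astart[id], 0)
          sc_u <- .c_of_A(pr$A0, pr); sc_q <- pr$A0 * sc_u
          r <- .newton(function(x) {
            A <- x[1]; u <- x[2]
            c((u - 4 * .c_of_A(A, pr) - W2[id]) / sc_u,
              (A * u - (p_c - .p_of_A(A, pr, p_ext)) / bed$R_dist) / sc_q)
          }, x0, scale = c(pr$A0, sc_u))
          warm[[key]] <- r$x
          A <- r$x[1]; u <- r$x[2]
          f <- .flux(A, A * u, pr)
          bF1[id] <<- f$F1; bF2[id] <<- f$F2
          bed_Qout[bi] <<- A * u
        }
      } else { # junction
        ends <- c(iseg, oseg)
        nin <- length(iseg)
        key <- paste0("n_", n)
        x0 <- if (!is.null(warm[[key]]))
          warm[[key]]
        else as.vector(rbind(c(Aend[iseg], Astart[oseg]),
                             rep(0, length(ends))))
        prs <- lapply(ends, function(id) S[[id]]$pr)
        sc_u <- .c_of_A(prs[[1]]$A0, prs[[1]])
        sc_p <- prs[[1]]$rho * sc_u^2
        sc_q <- prs[[1]]$A0 * sc_u
        r <- .newton(function(x) {
          A <- x[seq(1, length(x), 2)]
          u <- x[seq(2, length(x), 2)]
          res <- numeric(length(x))
          k <- 1
          for (e in seq_along(ends)) {
            pr <- prs[[e]]
            if (e <= nin)
              res[k] <- (u[e] + 4 * .c_of_A(A[e], pr) - W1[ends[e]]) / sc_u
            else
              res[k] <- (u[e] - 4 * .c_of_A(A[e], pr) - W2[ends[e]]) / sc_u
            k <- k + 1
          }
          p1 <- .p_of_A(A[1], prs[[1]], p_ext)
          for (e in seq_along(ends)[-1]) {
            res[k] <- (.p_of_A(A[e], prs[[e]], p_ext) - p1) / sc_p
            k <- k + 1
          }
          res[k] <- (sum(A[seq_len(nin)] * u[seq_len(nin)]) -
                       sum(A[-seq_len(nin)] * u[-seq_len(nin)])) / sc_q
          res
        }, x0, scale = as.vector(vapply(prs, function(pr)
          c(pr$A0, .c_of_A(pr$A0, pr)), numeric(2))))
        warm[[key]] <- r$x
        A <- r$x[seq(1, length(r$x), 2)]
        u <- r$x[seq(2, length(r$x), 2)]
        for (e in seq_along(ends)) {
          id <- ends[e]
          f <- .flux(A[e], A[e] * u[e], prs[[e]])
          if (e <= nin) { eF1[id] <<- f$F1; eF2[id] <<- f$F2 }
          else { bF1[id] <<- f$F1; bF2[id] <<- f$F2 }
        }
      }
    }
    for (n in nodes) solve_node(n)

    ## conservative update per segment
    for (id in ids) {
      s <- S[[id]]
      pr <- s$pr
      N <- s$N; dx <- s$dx
      A <- s$A; Q <- s$Q
      F1 <- Q
      F2 <- Q^2 / A + pr$beta * A^1.5 / (3 * pr$rho)
      kf <- 8 * pi * pr$mu / pr$rho # friction coefficient
      if (N > 1) {
        Aavg <- 0.5 * (A[-N] + A[-1]); Qavg <- 0.5 * (Q[-N] + Q[-1])
        iA <- Aavg - h / (2 * dx) * (F1[-1] - F1[-N])
        iQ <- Qavg - h / (2 * dx) * (F2[-1] - F2[-N]) -
          (h / 2) * kf * Qavg / Aavg
        hF1 <- iQ
        hF2 <- iQ^2 / iA + pr$beta * iA^1.5 / (3 * pr$rho)
      } else hF1 <- hF2 <- numeric(0)
      allF1 <- c(bF1[id], hF1, eF1[id])
      allF2 <- c(bF2[id], hF2, eF2[id])
      A <- A - h / dx * diff(allF1)
      ## semi-implicit friction keeps the discrete steady state balanced
      ## (flux divergence == friction) and is unconditionally stable
      Q <- (Q - h / dx * diff(allF2)) / (1 + h * kf / A)
      if (any(!is.finite(A)) || any(!is.finite(Q)))
        stop(sprintf("flow solver diverged (NaN) in segment %s at t = %.4g s",
                     id, t_now), call. = FALSE)
      if (any(A <= 0))
        stop(sprintf(
          "vessel collapse (A <= 0) in segment %s, cell %d, t = %.4g s",
          id, which(A <= 0)[1], t_now), call. = FALSE)
      S[[id]]$A <<- A
      S[[id]]$Q <<- Q
    }
    ## bed compliance update (explicit, so storage == integral of fluxes);
    ## terminal beds (no venous segment) drain through R_dist to p_out,
    ## which counts as network outflow
    for (bi in seq_along(model$beds)) {
      bed <- model$beds[[bi]]$bed
      qout <- if (is.na(bed_to[bi]))
        (bed_state[[bi]]$p_c - model$p_out) / bed$R_dist
      else bed_Qout[bi]
      if (is.na(bed_to[bi])) Q_out_net <- Q_out_net + qout
      bed_state[[bi]]$p_c <<- bed_state[[bi]]$p_c +
        (bed_Qin[bi] - qout) / bed$C * h
    }
    audit$inflow <<- audit$inflow + Q_in_net * h
    audit$outflow <<- audit$outflow + Q_out_net * h
    invisible(NULL)
  }

  for (step in seq_len(nt)) {
    t_now <- (step - 1) * dt
    ## CFL check / substepping
    lam <- max(vapply(ids, function(id) {
      s <- S[[id]]
      max(abs(s$Q / s$A) + .c_of_A(s$A, s$pr)) / s$dx
    }, numeric(1)))
    nsub <- max(1L, ceiling(dt * lam / cfl))
    if (nsub > 1 && !warned_cfl) {
      warning(sprintf(
        "time step reduced (x%d) to satisfy the CFL bound", nsub))
      warned_cfl <- TRUE
    }
    h <- dt / nsub
    for (sub in seq_len(nsub)) step_once(t_now + (sub - 1) * h, h)
    if (step %in% saved) snap()
  }

  tube1 <- sum(vapply(S, function(s) sum(s$A) * s$dx, numeric(1)))
  bedC <- if (length(model$beds))
    vapply(model$beds, function(b) b$bed$C, numeric(1)) else numeric(0)
  bed1 <- if (length(model$beds))
    sum(bedC * vapply(bed_state, `[[`, numeric(1), "p_c")) else 0
  audit$tube1 <- tube1
  audit$bed1 <- bed1
  for (id in ids) {
    pr <- S[[id]]$pr
    out[[id]]$p <- p_ext + pr$beta * (sqrt(out[[id]]$A) - sqrt(pr$A0))
    out[[id]]$u <- out[[id]]$Q / out[[id]]$A
    out[[id]]$x <- (seq_len(S[[id]]$N) - 0.5) * S[[id]]$dx
  }
  structure(list(segments = out, t = t_saved, dt = dt,
                 bed_p_c = bed_trace, model = model, audit = audit),
            class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("flow state: %d segments, t in [0, %.3f] s (%d snapshots)\n",
              length(x$segments), max(x$t), length(x$t)))
  invisible(x)
}

#' Global mass balance of a solved flow
#'
#' Inflow volume minus outflow volume minus the change in tube storage
#' (`integral of A dx`) and bed compliance storage, relative to the total
#' throughput. Interface fluxes are the solver's own, so for a correct
#' run this is at round-off level.
#'
#' @param state A `flow_state`.
#' @return List with the ledger volumes (m^3) and `relative_error`.
#' @export
flow_mass_balance <- function(state) {
  a <- state$audit
  stored <- (a$tube1 - a$tube0) + (a$bed1 - a$bed0)
  resid <- a$inflow - a$outflow - stored
  denom <- max(abs(a$inflow), abs(a$outflow), abs(stored), 1e-300)
  list(inflow = a$inflow, outflow = a$outflow, tube_storage = a$tube1 - a$tube0,
       bed_storage = a$bed1 - a$bed0, residual = resid,
       relative_error = abs(resid) / denom)
}

#' Probe a solved flow at a position along a segment
#'
#' @param state A `flow_state`.
#' @param segment_id Segment id.
#' @param x_fraction Position along the segment in `[0, 1]` (linear
#'   interpolation between cell centres; clamped at the ends).
#' @return Data frame with columns `t`, `p`, `Q`, `u`, `A`.
#' @export
export_timeseries <- function(state, segment_id, x_fraction = 0.5) {
  if (!segment_id %in% names(state$segments))
    stop("unknown segment: ", segment_id, call. = FALSE)
  stopifnot(x_fraction >= 0, x_fraction <= 1)
  s <- state$segments[[segment_id]]
  L <- max(s$x) + s$x[1] # cells at (i - 0.5) dx
  xq <- x_fraction * L
  interp <- function(M) {
    if (nrow(M) == 1) return(M[1, ])
    apply(M, 2, function(col) approx(s$x, col, xout = xq, rule = 2)$y)
  }
  data.frame(t = state$t, p = interp(s$p), Q = interp(s$Q),
             u = interp(s$u), A = interp(s$A))
}
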