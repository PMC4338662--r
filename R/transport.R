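#' Drug sources
#'
#' A drug enters the vascular system either as a time-varying point
#' source (e.g. needle injection at a position along a segment, mol/s),
#' as a distributed boundary condition along a segment (e.g. uptake from
#' the digestive tract, mol/(m s)), or as a distributed input into the
#' well-mixed tissue compartment of a named region (mol/s).
#'
#' @param kind `"point"`, `"distributed"` or `"region"`.
#' @param segment Segment id (point/distributed sources).
#' @param x_fraction Position along the segment in `[0, 1]` (point).
#' @param region Region anatomy term (region sources; matched against
#'   bed `region_term`s).
#' @param rate Function of time returning the rate (>= 0), or a single
#'   number for a constant rate.
#' @return A `drug_source` object.
#' @export
drug_source <- function(kind = c("point", "distributed", "region"),
                        segment = NULL, x_fraction = 0.5, region = NULL,
                        rate) {
  kind <- match.arg(kind)
  if (is.numeric(rate)) {
    r0 <- rate
    rate <- function(t) rep(r0, length(t))
  }
  if (kind %in% c("point", "distributed") && is.null(segment))
    stop("point/distributed sources need a segment id", call. = FALSE)
  if (kind == "region" && is.null(region))
    stop("region sources need a region term", call. = FALSE)
  structure(list(kind = kind, segment = segment, x_fraction = x_fraction,
                 region = if (is.null(region)) NULL else term_id(region),
                 rate = rate),
            class = "drug_source")
}

#' Build a steady flow state without running the flow solver
#'
#' Wraps prescribed constant area and flow per segment as a single-
#' snapshot `flow_state`, for driving the transport solver with an
#' analytically known velocity field.
#'
#' @param model A [flow_model()].
#' @param A Named list/vector of areas (m^2) per segment (recycled over
#'   cells).
#' @param Q Named list/vector of volumetric flows (m^3/s) per segment.
#' @return A `flow_state` with one snapshot at `t = 0`.
#' @export
steady_flow_state <- function(model, A, Q) {
  segs <- lapply(names(model$segments), function(id) {
    pr <- model$segments[[id]]$props
    N <- pr$n_grid
    Av <- rep(if (is.list(A)) A[[id]] else A[[id]], length.out = N)
    Qv <- rep(if (is.list(Q)) Q[[id]] else Q[[id]], length.out = N)
    list(A = matrix(Av, N, 1), Q = matrix(Qv, N, 1),
         p = matrix(0, N, 1), u = matrix(Qv / Av, N, 1),
         x = (seq_len(N) - 0.5) * pr$length / N)
  })
  names(segs) <- names(model$segments)
  structure(list(segments = segs, t = 0, dt = NA_real_,
                 bed_p_c = NULL, model = model,
                 audit = NULL),
            class = "flow_state")
}

#' Solve drug advection-diffusion over a solved flow
#'
#' Integrates, per segment,
#' `d(Ac)/dt + d(Qc)/dx = d/dx (A D dc/dx) + s(x, t)` with first-order
#' upwind advection and central diffusion (explicit, positivity-
#' preserving at the CFL bound, auto-substepped). Junction mixing is
#' flux-weighted and exactly conservative; vascular-bed compartments are
#' well-mixed (`V dc/dt = Q(c_in - c) - E Q c + source`) with extraction
#' fraction `E` removing drug irreversibly. Every mole is tracked in a
#' ledger (injected, in transit, in compartments, extracted, outflowed).
#'
#' @param flow A `flow_state` (from [solve_flow()] or
#'   [steady_flow_state()]).
#' @param sources List of [drug_source()]s.
#' @param D Molecular diffusivity (m^2/s).
#' @param t_end Simulated time (s).
#' @param dt Time step (s); `NULL` picks a stable step.
#' @param bed_volumes Compartment volumes (m^3), recycled over beds.
#' @param extraction Extraction fractions `E` in `[0, 1]`, recycled.
#' @param c_inlet Inflow concentration at the network root (mol/m^3),
#'   number or function of time.
#' @param save_every Save every this many steps.
#' @return A `concentration_field`: per segment `c` (cells x times),
#'   `t`, per-bed `c_bed` traces, the ledger, `D`.
#' @export
solve_transport <- function(flow, sources = list(), D = 0, t_end, dt = NULL,
                            bed_volumes = 1e-7, extraction = 0,
                            c_inlet = 0, save_every = 1L) {
  model <- flow$model
  ids <- names(model$segments)
  nbed <- length(model$beds)
  bedV <- rep(bed_volumes, length.out = max(nbed, 1))
  bedE <- rep(extraction, length.out = max(nbed, 1))
  stopifnot(all(bedE >= 0), all(bedE <= 1), D >= 0)
  if (is.numeric(c_inlet)) {
    ci0 <- c_inlet
    c_inlet <- function(t) ci0
  }
  ## geometry and flow lookup (piecewise-constant in time over snapshots)
  geom <- lapply(ids, function(id) {
    pr <- model$segments[[id]]$props
    N <- pr$n_grid
    list(N = N, dx = pr$length / N)
  })
  names(geom) <- ids
  snap_at <- function(t) {
    if (length(flow$t) == 1) return(1L)
    max(1L, findInterval(t + 1e-12, flow$t))
  }
  ## node topology as in the flow solver
  segdefs <- model$segments
  nodes <- unique(c(vapply(segdefs, `[[`, character(1), "from"),
                    vapply(segdefs, `[[`, character(1), "to")))
  ins <- lapply(nodes, function(n)
    ids[vapply(segdefs, function(s) s$to == n, logical(1))])
  outs <- lapply(nodes, function(n)
    ids[vapply(segdefs, function(s) s$from == n, logical(1))])
  names(ins) <- names(outs) <- nodes
  bed_from <- vapply(model$beds, function(b) b$from, character(1))
  bed_to <- vapply(model$beds, function(b)
    if (is.null(b$to) || is.na(b$to)) NA_character_ else b$to, character(1))

  ## stable step from the first snapshot
  k1 <- 1L
  umax <- max(vapply(ids, function(id)
    max(abs(flow$segments[[id]]$u[, k1])), numeric(1)), 1e-12)
  dxmin <- min(vapply(geom, `[[`, numeric(1), "dx"))
  if (is.null(dt)) {
    dt_adv <- 0.9 * dxmin / umax
    dt_dif <- if (D > 0) 0.4 * dxmin^2 / D else Inf
    dt <- min(dt_adv, dt_dif, t_end / 10)
  }
  nt <- ceiling(t_end / dt)
  saved <- unique(c(seq(0, nt, by = save_every), nt))
  ## state: cell masses (mol); compartments (mol)
  m <- lapply(ids, function(id) rep(0, geom[[id]]$N))
  names(m) <- ids
  m_bed <- rep(0, nbed)
  ledger <- list(injected = 0, extracted = 0, outflowed = 0, inflowed = 0)
  cfield <- lapply(ids, function(id)
    matrix(NA_real_, geom[[id]]$N, length(saved)))
  names(cfield) <- ids
  bed_trace <- if (nbed) matrix(NA_real_, nbed, length(saved)) else NULL
  ksave <- 1L
  conc_of <- function(id, k) m[[id]] / (flow$segments[[id]]$A[, k] * geom[[id]]$dx)
  snap <- function(k) {
    for (id in ids) cfield[[id]][, ksave] <<- conc_of(id, k)
    if (nbed) bed_trace[, ksave] <<- m_bed / bedV
    ksave <<- ksave + 1L
  }
  snap(1L)

  for (step in seq_len(nt)) {
    t_now <- (step - 1) * dt
    k <- snap_at(t_now)
    ## substep for stability against the current field
    umax <- max(vapply(ids, function(id)
      max(abs(flow$segments[[id]]$u[, k])), numeric(1)), 1e-12)
    ## combined advective + diffusive stability bound; a caller-chosen
    ## dt == dx/u runs at CFL 1 (exact advection for upwind)
    nsub <- max(1L, ceiling(dt * (umax / dxmin + 2 * D / dxmin^2) - 1e-9))
    h <- dt / nsub
    for (sub in seq_len(nsub)) {
      dm <- lapply(m, function(x) numeric(length(x)))
      dm_bed <- rep(0, nbed)
      ## interior fluxes
      for (id in ids) {
        g <- geom[[id]]
        A <- flow$segments[[id]]$A[, k]
        Q <- flow$segments[[id]]$Q[, k]
        cc <- m[[id]] / (A * g$dx)
        if (g$N > 1) {
          Qh <- 0.5 * (Q[-g$N] + Q[-1])
          cup <- ifelse(Qh >= 0, cc[-g$N], cc[-1])
          Fadv <- Qh * cup
          Ah <- 0.5 * (A[-g$N] + A[-1])
          Fdif <- -D * Ah * (cc[-1] - cc[-g$N]) / g$dx
          Fl <- Fadv + Fdif
          dm[[id]] <- dm[[id]] - c(Fl, 0) + c(0, Fl)
          ## flux Fl at interface i+1/2 leaves cell i, enters cell i+1
        }
      }
      ## node exchange: pool what flows out of segment ends into each
      ## node, redistribute flux-weighted into receiving ends
      for (n in nodes) {
        iseg <- ins[[n]]; oseg <- outs[[n]]
        pool <- 0       # mol/s entering the node
        recv <- list()  # receiving ends: list(id, end, Q)
        for (id in iseg) {
          g <- geom[[id]]
          Qe <- flow$segments[[id]]$Q[g$N, k]
          ce <- m[[id]][g$N] / (flow$segments[[id]]$A[g$N, k] * g$dx)
          if (Qe >= 0) {
            pool <- pool + Qe * ce
            dm[[id]][g$N] <- dm[[id]][g$N] - Qe * ce
          } else recv[[length(recv) + 1]] <- list(id = id, end = g$N, Q = -Qe)
        }
        for (id in oseg) {
          Qs <- flow$segments[[id]]$Q[1, k]
          cs <- m[[id]][1] / (flow$segments[[id]]$A[1, k] * geom[[id]]$dx)
          if (Qs >= 0) recv[[length(recv) + 1]] <- list(id = id, end = 1L, Q = Qs)
          else {
            pool <- pool + (-Qs) * cs
            dm[[id]][1] <- dm[[id]][1] - (-Qs) * cs
          }
        }
        if (identical(n, model$inlet)) {
          Qin <- sum(vapply(recv, `[[`, numeric(1), "Q"))
          pool <- pool + Qin * c_inlet(t_now)
          ledger$inflowed <- ledger$inflowed + Qin * c_inlet(t_now) * h
          ledger$injected <- ledger$injected + Qin * c_inlet(t_now) * h
        }
        ## beds attached to this node
        bi_art <- which(bed_from == n)
        bi_ven <- which(bed_to == n)
        for (bi in bi_art) { # pool drains into the bed compartment
          dm_bed[bi] <- dm_bed[bi] + pool
          pool <- 0
        }
        for (bi in bi_ven) { # bed feeds the venous side through this node
          g1 <- geom[[oseg[1]]]
          Qv <- flow$segments[[oseg[1]]]$Q[1, k]
          cb <- m_bed[bi] / bedV[bi]
          keep <- (1 - bedE[bi]) * Qv * cb
          ext <- bedE[bi] * Qv * cb
          dm_bed[bi] <- dm_bed[bi] - Qv * cb
          pool <- pool + keep
          ledger$extracted <- ledger$extracted + ext * h
        }
        Qrecv <- sum(vapply(recv, `[[`, numeric(1), "Q"))
        if (length(recv) && Qrecv > 0) {
          for (r in recv)
            dm[[r$id]][r$end] <- dm[[r$id]][r$end] + pool * r$Q / Qrecv
        } else if (pool > 0) { # pure outlet node: mass leaves the system
          ledger$outflowed <- ledger$outflowed + pool * h
        }
        if (length(recv) && Qrecv > 0) pool <- 0
      }
      ## terminal beds: drain to the outside at the bed through-flow
      for (bi in seq_len(nbed)) {
        if (!is.na(bed_to[bi])) next
        id <- ins[[bed_from[bi]]][1]
        Qe <- flow$segments[[id]]$Q[geom[[id]]$N, k]
        cb <- m_bed[bi] / bedV[bi]
        dm_bed[bi] <- dm_bed[bi] - Qe * cb
        ledger$extracted <- ledger$extracted + bedE[bi] * Qe * cb * h
        ledger$outflowed <- ledger$outflowed + (1 - bedE[bi]) * Qe * cb * h
      }
      ## sources
      for (src in sources) {
        r <- src$rate(t_now)
        if (r < 0) stop("source rate must be >= 0", call. = FALSE)
        if (src$kind == "point") {
          g <- geom[[src$segment]]
          cell <- min(g$N, max(1L, ceiling(src$x_fraction * g$N)))
          dm[[src$segment]][cell] <- dm[[src$segment]][cell] + r
          ledger$injected <- ledger$injected + r * h
        } else if (src$kind == "distributed") {
          g <- geom[[src$segment]]
          dm[[src$segment]] <- dm[[src$segment]] + r * g$dx
          ledger$injected <- ledger$injected + r * g$dx * g$N * h
        } else {
          hit <- which(vapply(model$beds, function(b)
            identical(b$bed$region_term, src$region), logical(1)))
          if (!length(hit))
            stop("no bed with region term ", src$region, call. = FALSE)
          dm_bed[hit[1]] <- dm_bed[hit[1]] + r
          ledger$injected <- ledger$injected + r * h
        }
      }
      ## advance
      for (id in ids) m[[id]] <- m[[id]] + h * dm[[id]]
      if (nbed) m_bed <- m_bed + h * dm_bed
      neg <- min(0, min(vapply(m, min, numeric(1))),
                 if (nbed) min(m_bed) else 0)
      tot <- max(ledger$injected, 1e-300)
      if (neg < -1e-9 * tot)
        stop("negative concentration beyond tolerance: scheme violation",
             call. = FALSE)
    }
    if (step %in% saved) snap(snap_at(step * dt))
  }
  structure(list(c = cfield, t = saved * dt,
                 c_bed = bed_trace, ledger = ledger,
                 in_transit = sum(vapply(m, sum, numeric(1))),
                 in_compartments = if (nbed) sum(m_bed) else 0,
                 D = D, flow = flow),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf(
    "concentration field: %d segments, t in [0, %.3f] s; injected %.3e mol\n",
    length(x$c), max(x$t), x$ledger$injected))
  invisible(x)
}

#' Audit the drug mass balance
#'
#' Balances injected drug against mass in transit in the vessels, mass in
#' tissue compartments, mass extracted by beds, and mass flushed out of
#' open outlets.
#'
#' @param field A `concentration_field`.
#' @return List of ledger entries (mol) plus `relative_error`
#'   (|injected - accounted| / injected; 0 when nothing was injected and
#'   nothing is present).
#' @export
mass_audit <- function(field) {
  led <- field$ledger
  accounted <- field$in_transit + field$in_compartments +
    led$extracted + led$outflowed
  resid <- led$injected - accounted
  denom <- max(abs(led$injected), abs(accounted))
  list(injected = led$injected, in_transit = field$in_transit,
       in_compartments = field$in_compartments,
       extracted = led$extracted, outflowed = led$outflowed,
       residual = resid,
       relative_error = if (denom == 0) 0 else abs(resid) / denom)
}

#' Receptor binding models
#'
#' Mass-action ligand-receptor kinetics
#' `d[LR]/dt = k_on c (R_total - [LR]) - k_off [LR]`, annotated with the
#' cell type expressing the receptor and the anatomy term of its tissue;
#' the annotation is checked against a PTM before coupling.
#'
#' @param k_on Association rate (per concentration unit of `c`, per s).
#' @param k_off Dissociation rate (1/s).
#' @param R_total Total receptor concentration (same unit family as the
#'   bound complex).
#' @param anatomy_term,cell_type Annotation terms.
#' @return A `receptor_model` object.
#' @export
receptor_model <- function(k_on, k_off, R_total, anatomy_term, cell_type) {
  stopifnot(k_on > 0, k_off > 0, R_total > 0)
  structure(list(k_on = k_on, k_off = k_off, R_total = R_total,
                 annotation = list(anatomy_term = term_id(anatomy_term),
                                   cell_types = cell_type)),
            class = "receptor_model")
}

#' Couple a tissue drug concentration to a receptor model
#'
#' Refuses (listing the reasons) unless the receptor model's annotation
#' is compatible with the PTM: the modelled cell type must be provably
#' within diffusion distance in that pFTU. The bound fraction is then
#' integrated with an exact exponential update per sample interval (the
#' ODE is linear in the bound complex for piecewise-constant c), which is
#' unconditionally stable for stiff rate constants.
#'
#' @param conc Data frame with columns `t` (s) and `c` (tissue drug
#'   concentration), or a function of t sampled at `times`.
#' @param model A [receptor_model()].
#' @param ptm A [primary_tissue_motif()] the model must be compatible
#'   with.
#' @param times Sample times when `conc` is a function.
#' @return Data frame `t`, `c`, `bound_fraction` (in `[0, 1]`).
#' @export
couple_receptor <- function(conc, model, ptm, times = NULL) {
  gate <- ptm_compatible(ptm, model$annotation)
  if (!gate$compatible)
    stop("receptor model incompatible with PTM: ",
         paste(gate$reasons, collapse = ", "), call. = FALSE)
  if (is.function(conc)) {
    stopifnot(!is.null(times))
    conc <- data.frame(t = times, c = conc(times))
  }
  tt <- conc$t
  cc <- conc$c
  if (any(cc < 0)) stop("concentration must be >= 0", call. = FALSE)
  n <- length(tt)
  LR <- numeric(n)
  for (i in seq_len(n - 1)) {
    dtloc <- tt[i + 1] - tt[i]
    kc <- model$k_on * cc[i]
    rate <- kc + model$k_off
    LR_eq <- model$R_total * kc / rate
    LR[i + 1] <- LR_eq + (LR[i] - LR_eq) * exp(-rate * dtloc)
  }
  data.frame(t = tt, c = cc, bound_fraction = LR / model$R_total)
}
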