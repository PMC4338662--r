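#' Workflow configuration
#'
#' Defaults bind the pipeline to the pFTU template geometry (80 um
#' diameter, 60 um segment length, 40 um dilation radius); all values can
#' be overridden. The configuration is echoed into every run manifest.
#'
#' @param out_dir Output directory.
#' @param seed Seed for every stochastic stage.
#' @param radius_um,seg_length_um pFTU template parameters.
#' @param stack_sections,stack_size Serial-stack fixture size.
#' @param volume_dims,voxel_size_um Tissue volume fixture geometry.
#' @param tree_depth Vascular tree depth.
#' @param flow_t_end,drug_t_end Simulated times (s); the transport window
#'   is long enough for a root-injected bolus to reach the beds.
#' @return A `workflow_config` list.
#' @export
workflow_config <- function(out_dir = tempfile("circuitboard_run_"),
                            seed = 1L,
                            radius_um = PFTU_DILATION_RADIUS_UM,
                            seg_length_um = PFTU_SEGMENT_LENGTH_UM,
                            stack_sections = 6L, stack_size = 48L,
                            volume_dims = c(36L, 36L, 18L),
                            voxel_size_um = c(4, 4, 8),
                            tree_depth = 2L,
                            flow_t_end = 0.25, drug_t_end = 3) {
  structure(list(out_dir = out_dir, seed = seed, radius_um = radius_um,
                 seg_length_um = seg_length_um,
                 diameter_um = 2 * radius_um,
                 stack_sections = stack_sections, stack_size = stack_size,
                 volume_dims = volume_dims, voxel_size_um = voxel_size_um,
                 tree_depth = tree_depth, flow_t_end = flow_t_end,
                 drug_t_end = drug_t_end),
            class = "workflow_config")
}

#' Run the full desk-scale workflow on synthetic fixtures
#'
#' Executes, in order: fixture generation, serial-section alignment,
#' channel parcellation into pFTUs, cell annotation and PTM derivation,
#' the PTM compatibility gate, pulsatile flow solution over a vascular
#' tree, and drug transport with receptor coupling. Each stage's outputs
#' are written under `config$out_dir` and recorded (with content hashes)
#' in a JSON run manifest; a stage failure is caught and the manifest
#' records the partial completion.
#'
#' @param config A [workflow_config()].
#' @return The manifest (list), invisibly written to
#'   `<out_dir>/manifest.json`.
#' @export
run_workflow <- function(config = workflow_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config),
                   package_version = as.character(
                     utils::packageVersion("circuitboard")),
                   stages = list())
  shared <- new.env(parent = emptyenv())
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    entry <- list(status = if (res$ok) "completed" else "failed",
                  seconds = round(proc.time()[["elapsed"]] - t0, 3))
    if (!res$ok) entry$error <- res$error
    if (res$ok && !is.null(res$value$files)) {
      entry$files <- lapply(res$value$files, function(f)
        list(path = basename(f), md5 = unname(tools::md5sum(f))))
    }
    if (res$ok && !is.null(res$value$info)) entry$info <- res$value$info
    manifest$stages[[name]] <<- entry
    if (!res$ok) stop("stage '", name, "' failed: ", res$error, call. = FALSE)
    invisible(res$value)
  }
  finish <- function() {
    path <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(manifest)
  }
  on.exit(finish())

  stage("fixtures", function() {
    cx <- config$volume_dims * config$voxel_size_um / 2
    tube <- list(polyline = rbind(
      c(8, cx[2], cx[3]),
      c(config$volume_dims[1] * config$voxel_size_um[1] - 8, cx[2], cx[3])),
      radius_um = 10, label = 1L)
    fix <- make_tube_volume(config$volume_dims, config$voxel_size_um,
                            tubes = list(tube),
                            nuclei = list(
                              list(ct_term = "CT:endothelial-cell", n = 12,
                                   band = c(-10, 4)),
                              list(ct_term = "CT:pericyte", n = 6,
                                   band = c(2, 15))),
                            seed = config$seed)
    volp <- file.path(config$out_dir, "volume.tif")
    write_volume(fix$volume, volp)
    marksp <- file.path(config$out_dir, "marks.csv")
    write_cell_marks(fix$marks, marksp)
    stk <- make_misaligned_stack(texture_image(config$stack_size,
                                               seed = config$seed),
                                 config$stack_sections, shift_range_px = 4,
                                 theta_range_deg = 2, seed = config$seed + 1)
    tree <- make_vascular_tree(config$tree_depth, seed = config$seed + 2)
    netp <- file.path(config$out_dir, "network.json")
    write_network(tree$network, netp)
    shared$fix <- fix; shared$stk <- stk; shared$tree <- tree
    list(files = list(volp, marksp, netp))
  })

  stage("align", function() {
    res <- align_stack(shared$stk$sections, seed = config$seed)
    tabp <- file.path(config$out_dir, "transforms.csv")
    write.csv(res$table, tabp, row.names = FALSE)
    shared$stack <- res$stack
    list(files = list(tabp),
         info = list(axial_extent_um = res$stack$axial_extent_um))
  })

  stage("parcellate", function() {
    vol <- shared$fix$volume
    par <- parcellate(vol, radius_um = config$radius_um,
                      seg_length_um = config$seg_length_um,
                      term_map = list("1" = "FMA:capillary-fixture"))
    outp <- write_pftus(par$pftus, vol, file.path(config$out_dir, "pftus"))
    shared$par <- par
    list(files = list(outp), info = list(n_pftus = length(par$pftus)))
  })

  stage("annotate", function() {
    vol <- shared$fix$volume
    mem <- assign_cells(shared$fix$marks, shared$par$pftus, vol)
    ptms <- lapply(shared$par$pftus, derive_ptm, membership = mem,
                   marks = shared$fix$marks)
    ptmp <- file.path(config$out_dir, "ptms.json")
    write_ptms(ptms, ptmp)
    shared$ptms <- ptms
    nonempty <- sum(vapply(ptms, function(p) length(p$cell_types) > 0,
                           logical(1)))
    list(files = list(ptmp), info = list(n_ptms = length(ptms),
                                         n_nonempty = nonempty))
  })

  stage("ptm_gate", function() {
    ptm <- NULL
    for (p in shared$ptms)
      if ("CT:endothelial-cell" %in% p$cell_types) { ptm <- p; break }
    if (is.null(ptm)) stop("no pFTU contains the modelled cell type")
    gate <- ptm_compatible(ptm, list(anatomy_term = ptm$anatomy_term,
                                     cell_types = "CT:endothelial-cell"))
    if (!gate$compatible)
      stop("PTM gate refused: ", paste(gate$reasons, collapse = ", "))
    shared$gated_ptm <- ptm
    list(info = list(pftu_id = ptm$pftu_id))
  })

  stage("flow", function() {
    tree <- shared$tree
    inflow <- sine_inflow(Q_mean = 8e-7, Q_amp = 3e-7, period_s = 0.25)
    fs <- solve_flow(tree$flow, inflow, t_end = config$flow_t_end,
                     save_every = 10L)
    probe <- export_timeseries(fs, names(tree$flow$segments)[1], 0.5)
    probep <- file.path(config$out_dir, "flow_probe.csv")
    write.csv(probe, probep, row.names = FALSE)
    shared$fs <- fs
    list(files = list(probep),
         info = list(mass_balance_rel_error =
                       flow_mass_balance(fs)$relative_error))
  })

  stage("drug", function() {
    fs <- shared$fs
    root <- names(fs$model$segments)[1]
    src <- drug_source("point", segment = root, x_fraction = 0.1,
                       rate = function(t) ifelse(t < 0.05, 2e-6, 0))
    cf <- solve_transport(fs, list(src), D = 1e-9, dt = 0.02,
                          t_end = config$drug_t_end, save_every = 5L)
    aud <- mass_audit(cf)
    ## couple the first bed's tissue concentration to a receptor model
    ptm <- shared$gated_ptm
    rec <- receptor_model(k_on = 1e3, k_off = 0.1, R_total = 1e-3,
                          anatomy_term = ptm$anatomy_term,
                          cell_type = "CT:endothelial-cell")
    cb <- data.frame(t = cf$t, c = cf$c_bed[1, ])
    bf <- couple_receptor(cb, rec, ptm)
    drugp <- file.path(config$out_dir, "drug_tissue.csv")
    write.csv(bf, drugp, row.names = FALSE)
    list(files = list(drugp),
         info = list(mass_audit_rel_error = aud$relative_error,
                     peak_bound_fraction = max(bf$bound_fraction)))
  })

  finish()
  on.exit(NULL)
  invisible(manifest)
}
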