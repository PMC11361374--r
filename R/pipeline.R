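#' Run the phenotyping pipeline from a single config
#'
#' Orchestrates the stages in dependency order — `simulate` (two-channel
#' nucleus or foci images), `segment`, `measure` (morphometry + bleb
#' calling), `foci`, `report`, plus the stand-alone `frap` (trace fitting)
#' and `de` (count filtering) stages — writing images, per-nucleus and
#' summary CSVs, and a machine-readable `manifest.json` into `out_dir`.
#' Every default parameter in force is echoed into the manifest, and the
#' manifest records the MD5 of the config actually used, so unstated
#' choices are always visible in outputs. Rerunning an identical config
#' over identical inputs reproduces the CSVs bit for bit (stochastic
#' stages are pinned by the recorded seed).
#'
#' @param config Path to a YAML file or an equivalent named list. Top-level
#'   fields: `seed`, `stages` (subset of the above, executed in canonical
#'   order), and one parameter block per stage (`simulate`, `segment`,
#'   `measure`, `foci`, `frap`, `de`).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a YAML path or a list", call. = FALSE)
  stages <- cfg$stages %||% c("simulate", "segment", "measure", "report")
  known <- c("simulate", "segment", "measure", "foci", "frap", "de", "report")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  stages <- known[known %in% stages]   # canonical order
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  seed <- cfg$seed %||% 1L
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = seed, stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- res
  }

  if ("simulate" %in% stages) run_stage("simulate", function()
    stage_simulate(cfg$simulate %||% list(), seed, out_dir, state))
  if ("segment" %in% stages) run_stage("segment", function()
    stage_segment(cfg$segment %||% list(), out_dir, state))
  if ("measure" %in% stages) run_stage("measure", function()
    stage_measure(cfg$measure %||% list(), out_dir, state))
  if ("foci" %in% stages) run_stage("foci", function()
    stage_foci(cfg$foci %||% list(), out_dir, state))
  if ("frap" %in% stages) run_stage("frap", function()
    stage_frap(cfg$frap %||% list(), seed, out_dir))
  if ("de" %in% stages) run_stage("de", function()
    stage_de(cfg$de %||% list(), seed, out_dir))
  if ("report" %in% stages) run_stage("report", function()
    stage_report(out_dir, state))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

stage_simulate <- function(p, seed, out_dir, state) {
  kind <- p$kind %||% "nuclei"
  n_images <- p$n_images %||% 1L
  spec_args <- p[setdiff(names(p), c("kind", "n_images"))]
  imgs <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    spec <- do.call(nucleus_image_spec,
                    c(spec_args, list(seed = seed + i - 1L)))
    imgs[[i]] <- if (kind == "foci") make_foci_image(spec)
    else make_nucleus_image(spec)
    for (ch in intersect(names(imgs[[i]]), c("dapi", "lamin", "marker")))
      write_image(imgs[[i]][[ch]],
                  file.path(out_dir, sprintf("img%02d_%s.tif", i, ch)))
  }
  state$images <- imgs
  state$kind <- kind
  c(list(kind = kind, n_images = n_images),
    spec_params_echo(do.call(nucleus_image_spec,
                             c(spec_args, list(seed = seed)))))
}

spec_params_echo <- function(spec) {
  keep <- setdiff(names(unclass(spec)), "seed")
  lapply(unclass(spec)[keep], function(v) if (is.function(v)) "function" else v)
}

stage_segment <- function(p, out_dir, state) {
  if (is.null(state$images))
    stop("segment requires the simulate stage (or pre-loaded images)",
         call. = FALSE)
  params <- do.call(segmentation_params, p)
  state$masks <- lapply(state$images, function(im) {
    dapi <- segment_nuclei(im$dapi, params)
    lamin <- if (!is.null(im$lamin)) segment_nuclei(im$lamin, params)
    list(dapi = dapi, lamin = lamin)
  })
  c(list(n_images = length(state$masks)), unclass(params))
}

stage_measure <- function(p, out_dir, state) {
  if (is.null(state$masks)) stop("measure requires the segment stage",
                                 call. = FALSE)
  bp <- do.call(bleb_params, p)
  recs <- list()
  for (i in seq_along(state$masks)) {
    m <- state$masks[[i]]
    im <- state$images[[i]]
    rec <- measure_nuclei(m$dapi, list(dapi = im$dapi),
                          image_id = sprintf("img%02d", i))
    if (!is.null(m$lamin) && m$lamin$n_objects > 0) {
      bl <- detect_blebs(m$dapi, m$lamin, bp)
      rec <- merge(rec, bl$nuclei[, c("label", "n_blebs", "bleb_area_total")],
                   by = "label", all.x = TRUE)
    }
    recs[[i]] <- rec
  }
  records <- do.call(rbind, recs)
  records <- records[order(records$image, records$label), ]
  write_table(records, file.path(out_dir, "nuclei.csv"))
  state$records <- records
  c(list(n_nuclei = nrow(records)), unclass(bp))
}

stage_foci <- function(p, out_dir, state) {
  if (is.null(state$masks)) stop("foci requires the segment stage",
                                 call. = FALSE)
  fp <- do.call(foci_params, p)
  rows <- list()
  for (i in seq_along(state$masks)) {
    im <- state$images[[i]]
    marker <- im$marker %||% im$dapi
    enh <- enhance_speckles(marker, fp$feature_size)
    det <- detect_foci(enh, state$masks[[i]]$dapi, fp)
    det$counts$image <- sprintf("img%02d", i)
    rows[[i]] <- det$counts
  }
  counts <- do.call(rbind, rows)
  write_table(counts[, c("image", "label", "count")],
              file.path(out_dir, "foci_counts.csv"))
  state$foci_counts <- counts
  c(list(n_nuclei = nrow(counts),
         pct_foci_positive = if (any(!is.na(counts$count)))
           percent_foci_positive(counts) else NA),
    unclass(fp))
}

stage_frap <- function(p, seed, out_dir) {
  input <- p$input
  n_prebleach <- p$n_prebleach %||% 3L
  fits <- list(); cond <- character()
  if (!is.null(input)) {
    files <- sort(list.files(input, pattern = "\\.csv$", full.names = TRUE))
    if (!length(files)) stop("no trace CSVs found in frap input", call. = FALSE)
    for (f in files) {
      tr <- utils::read.csv(f)
      trace <- frap_trace(tr$time_s, tr$roi_intensity, tr$ref_intensity,
                          n_prebleach)
      fits[[length(fits) + 1L]] <- fit_recovery(bleach_correct(trace))
      cond <- c(cond, tr$condition[1] %||% "all")
    }
  } else {
    n_traces <- p$n_traces %||% 25L
    spec_args <- p[setdiff(names(p), c("input", "n_traces", "n_prebleach"))]
    for (i in seq_len(n_traces)) {
      spec <- do.call(frap_sim_spec,
                      c(spec_args, list(n_prebleach = n_prebleach,
                                        seed = seed + i - 1L)))
      fits[[i]] <- fit_recovery(bleach_correct(simulate_frap(spec)))
      cond <- c(cond, "simulated")
    }
  }
  per_fit <- data.frame(
    condition = cond,
    y0 = vapply(fits, `[[`, numeric(1), "y0"),
    a = vapply(fits, `[[`, numeric(1), "a"),
    b = vapply(fits, `[[`, numeric(1), "b"),
    immobile_fraction_pct = vapply(fits, `[[`, numeric(1),
                                   "immobile_fraction_pct"),
    t_half = vapply(fits, `[[`, numeric(1), "t_half"),
    converged = vapply(fits, `[[`, logical(1), "converged"))
  write_table(per_fit, file.path(out_dir, "frap_fits.csv"))
  sm <- summarize_frap(fits, cond)
  write_table(sm$summary, file.path(out_dir, "frap_summary.csv"))
  list(n_fits = length(fits), n_converged = sum(per_fit$converged),
       n_prebleach = n_prebleach)
}

stage_de <- function(p, seed, out_dir) {
  padj_max <- p$padj_max %||% 0.001
  lfc_min <- p$lfc_min %||% 2
  if (!is.null(p$results)) {
    res <- utils::read.csv(p$results)
  } else if (!is.null(p$counts)) {
    counts <- as.matrix(utils::read.csv(p$counts, row.names = 1))
    groups <- utils::read.csv(p$groups)$group
    res <- per_gene_test(counts, groups)
  } else {
    spec_args <- p[intersect(names(p), names(formals(count_sim_spec)))]
    sim <- simulate_counts(do.call(count_sim_spec,
                                   c(spec_args, list(seed = seed))))
    res <- per_gene_test(sim$counts, sim$groups)
  }
  sub <- de_subset(res, padj_max = padj_max, lfc_min = lfc_min)
  write_table(sub$results, file.path(out_dir, "de_results.csv"))
  writeLines(sub$up, file.path(out_dir, "de_up.txt"))
  writeLines(sub$down, file.path(out_dir, "de_down.txt"))
  list(n_genes = nrow(sub$results), n_up = length(sub$up),
       n_down = length(sub$down), padj_max = padj_max, lfc_min = lfc_min)
}

stage_report <- function(out_dir, state) {
  if (is.null(state$records)) return(list(note = "nothing to report"))
  rec <- state$records
  out <- list(n_nuclei = nrow(rec),
              mean_form_factor = mean(rec$form_factor))
  if ("n_blebs" %in% names(rec)) {
    scored <- rec[!is.na(rec$n_blebs), ]
    out$pct_blebbing <- if (nrow(scored)) percent_blebbing(scored) else NA
  }
  write_table(data.frame(metric = names(out),
                         value = unlist(lapply(out, as.numeric))),
              file.path(out_dir, "summary.csv"))
  out
}
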