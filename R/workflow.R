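#' Assemble a workflow configuration
#'
#' @param stages character vector of stage names, run in order; any subset
#'   of `"structural"`, `"fcstrength"`, `"seedmap"`, `"topology"`,
#'   `"graph"` (the synthetic dataset is generated whenever at least one
#'   stage needs it).
#' @param out_dir output directory for reports and the manifest.
#' @param seed master integer seed; every stage derives its RNG state from
#'   it, so a rerun with the same config is bit-identical.
#' @param synth named list of [synth_config()] overrides.
#' @param fcstrength list: `stats` (subset of mean/median), `fwhm_mm`
#'   (numeric vector), `threshold`.
#' @param structural list: `vertexwise_p`, `n_perm`, `jaccard_parcels`.
#' @param seedmap list: `seed_parcels` (names in the synthetic scheme),
#'   `n_perm`, `min_cluster_area_mm2`.
#' @param topology list: `n_perm`, `thresholds`, `smooth_sigma_mm`.
#' @param graph list: `r_threshold`.
#' @return List of class `run_config`.
#' @export
run_config <- function(stages = c("structural", "fcstrength", "seedmap",
                                  "topology", "graph"),
                       out_dir, seed = 1L,
                       synth = list(),
                       structural = list(),
                       fcstrength = list(),
                       seedmap = list(),
                       topology = list(),
                       graph = list()) {
  known <- c("structural", "fcstrength", "seedmap", "topology", "graph")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  defaults <- list(
    structural = list(vertexwise_p = 1e-4, n_perm = 1000,
                      jaccard_parcels = NULL),
    fcstrength = list(stats = "mean", fwhm_mm = 0, threshold = 0.3),
    seedmap = list(seed_parcels = NULL, n_perm = 1000,
                   min_cluster_area_mm2 = 50),
    topology = list(n_perm = 1000, thresholds = c(0.3, 0.4, 0.5, 0.6),
                    smooth_sigma_mm = 2.12),
    graph = list(r_threshold = 0.3)
  )
  cfg <- list(stages = stages, out_dir = out_dir, seed = as.integer(seed),
              synth = synth)
  for (st in names(defaults)) {
    cfg[[st]] <- utils::modifyList(defaults[[st]], get(st))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full paired-pipeline comparison workflow
#'
#' Generates the synthetic paired dataset, executes the requested stages in
#' order, writes every report under `config$out_dir` (TSV for tables, JSON
#' for cluster/concordance summaries) and finishes with a `manifest.json`
#' recording the package version, seed, parameters, and an md5 checksum per
#' output file. A rerun with the same config produces identical checksums.
#' A stage failure halts the run with the stage name after writing a
#' partial manifest.
#'
#' @param config a `run_config`.
#' @return The manifest, invisibly.
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  add_tsv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    data.table::fwrite(df, p, sep = "\t")
    outputs <<- c(outputs, name)
  }
  add_json <- function(x, name) {
    p <- file.path(config$out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    outputs <<- c(outputs, name)
  }
  finish <- function(failed_stage = NULL) {
    manifest <- list(
      package = "neuroconcord",
      version = as.character(utils::packageVersion("neuroconcord")),
      seed = config$seed,
      stages = config$stages,
      parameters = config[setdiff(names(config), c("stages", "out_dir"))],
      outputs = as.list(stats::setNames(
        unname(tools::md5sum(file.path(config$out_dir, outputs))), outputs
      ))
    )
    if (!is.null(failed_stage)) manifest$failed_stage <- failed_stage
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest
  }
  if (!length(config$stages)) {
    return(invisible(finish()))
  }

  scfg <- do.call(synth_config, utils::modifyList(
    config$synth, list(rng_seed = config$seed)
  ))
  message("[synth] generating ", scfg$n_subjects, " paired subjects")
  ds <- generate_paired_dataset(scfg)
  bundles <- ds$subjects
  surface <- bundles[[1]]$A$surface

  run_stage <- function(stage, fn) {
    message("[", stage, "] running")
    tryCatch(fn(), error = function(e) {
      finish(failed_stage = stage)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  for (stage in config$stages) {
    if (stage == "structural") run_stage(stage, function() {
      p <- config$structural
      for (q in c("thickness", "gyrification", "volume")) {
        rep <- parcel_structural_comparison(bundles, q)
        add_tsv(as.data.frame(rep), sprintf("structural_%s.tsv", q))
      }
      maps_a <- sapply(bundles, function(s) s$A$thickness$values)
      maps_b <- sapply(bundles, function(s) s$B$thickness$values)
      vcr <- vertexwise_paired_comparison(
        maps_a, maps_b, surface, vertexwise_p = p$vertexwise_p,
        n_perm = p$n_perm, seed = config$seed + 1L
      )
      add_json(cluster_report_json(vcr), "structural_thickness_clusters.json")
      parcels <- p$jaccard_parcels
      if (is.null(parcels)) parcels <- bundles[[1]]$A$scheme$parcel_names
      jac <- t(sapply(parcels, function(pc) {
        j <- vapply(bundles, function(s) {
          jaccard(s$A$scheme, s$B$scheme, pc)
        }, numeric(1))
        c(mean_jaccard = mean(j), sd_jaccard = stats::sd(j))
      }))
      add_tsv(data.frame(parcel = parcels, jac), "jaccard.tsv")
    })
    if (stage == "fcstrength") run_stage(stage, function() {
      p <- config$fcstrength
      for (st in p$stats) for (fw in p$fwhm_mm) {
        rep <- compare_fc_strength(bundles, stat = st, smoothing_fwhm = fw,
                                   threshold = p$threshold)
        add_tsv(as.data.frame(rep),
                sprintf("fcstrength_%s_fwhm%g.tsv", st, fw))
      }
    })
    if (stage == "seedmap") run_stage(stage, function() {
      p <- config$seedmap
      seeds <- p$seed_parcels
      if (is.null(seeds)) seeds <- bundles[[1]]$A$scheme$parcel_names[1]
      for (sp in seeds) {
        ma <- sapply(bundles, function(s) seed_vertex_map(s$A, sp)$values)
        mb <- sapply(bundles, function(s) seed_vertex_map(s$B, sp)$values)
        keep <- stats::complete.cases(ma) & stats::complete.cases(mb)
        # opposite-hemisphere vertices are missing; zero them for the group test
        ma[!keep, ] <- 0
        mb[!keep, ] <- 0
        vcr <- network_group_comparison(
          ma, mb, surface, min_cluster_area_mm2 = p$min_cluster_area_mm2,
          n_perm = p$n_perm, seed = config$seed + 2L
        )
        add_json(cluster_report_json(vcr),
                 sprintf("seedmap_%s_clusters.json", sp))
      }
    })
    if (stage == "topology") run_stage(stage, function() {
      p <- config$topology
      rois <- names(scfg$seed_rois)
      set.seed(config$seed + 3L)
      seed_maps <- lapply(bundles, function(s) {
        list(
          A = stats::setNames(lapply(rois, function(r) {
            generate_seed_volume(scfg, r, "A")
          }), rois),
          B = stats::setNames(lapply(rois, function(r) {
            generate_seed_volume(scfg, r, "B")
          }), rois)
        )
      })
      psa <- peak_shift_analysis(seed_maps, rois[1], rois[2])
      add_tsv(psa$distances, "topology_distances.tsv")
      add_json(list(
        per_roi_tests = psa$per_roi_tests,
        delta_test = psa$delta_test
      ), "topology_peak_shift_tests.json")
      err_rows <- list()
      for (s in seq_along(seed_maps)) for (r in rois) {
        for (em in error_maps(seed_maps[[s]]$A[[r]], seed_maps[[s]]$B[[r]],
                              thresholds = p$thresholds)) {
          err_rows[[length(err_rows) + 1L]] <- data.frame(
            subject = s, roi = r, threshold = em$threshold,
            mean_error = em$mean_error
          )
        }
      }
      err_df <- do.call(rbind, err_rows)
      add_tsv(err_df, "topology_error_means.tsv")
      err_tests <- lapply(p$thresholds, function(th) {
        ex <- err_df[err_df$threshold == th & err_df$roi == rois[1], ]
        ey <- err_df[err_df$threshold == th & err_df$roi == rois[2], ]
        c(list(threshold = th),
          paired_t(ex$mean_error[order(ex$subject)],
                   ey$mean_error[order(ey$subject)]))
      })
      add_json(err_tests, "topology_error_tests.json")
      tf <- lapply(stats::setNames(rois, rois), function(r) {
        diffs <- lapply(seed_maps, function(s) {
          d <- s$B[[r]]
          d$array <- d$array - s$A[[r]]$array
          smooth_volume(d, p$smooth_sigma_mm)
        })
        res <- tfce_permutation_fwe(diffs, n_perm = p$n_perm,
                                    seed = config$seed + 4L)
        list(n_permutations = res$n_permutations,
             n_significant_voxels = res$n_significant,
             min_pfwe = min(res$pfwe$array[res$pfwe$mask]))
      })
      add_json(tf, "topology_tfce.json")
    })
    if (stage == "graph") run_stage(stage, function() {
      p <- config$graph
      gc <- graph_concordance(bundles, r_threshold = p$r_threshold)
      add_json(as.list(gc$concordance), "graph_concordance.json")
      for (mn in names(gc$metric_matrices)) {
        for (pp in c("A", "B")) {
          m <- gc$metric_matrices[[mn]][[pp]]
          add_tsv(data.frame(parcel = rownames(m), m, check.names = FALSE),
                  sprintf("graph_%s_%s.tsv", mn, pp))
        }
      }
    })
  }
  invisible(finish())
}

# serializable view of a vertex_cluster_report
cluster_report_json <- function(vcr) {
  list(
    n_permutations = vcr$n_permutations,
    vertexwise_threshold_p = vcr$vertexwise_threshold_p,
    min_cluster_area_mm2 = vcr$min_cluster_area_mm2,
    clusters = lapply(vcr$clusters, function(cl) {
      list(n_vertices = length(cl$vertices), vertices = cl$vertices,
           mass = cl$mass, area_mm2 = cl$area_mm2,
           p_corrected = cl$p_corrected,
           significant = isTRUE(cl$significant))
    }),
    excluded_clusters = lapply(vcr$excluded_clusters, function(cl) {
      list(n_vertices = length(cl$vertices), mass = cl$mass,
           area_mm2 = cl$area_mm2)
    })
  )
}
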