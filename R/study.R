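#' Configuration of a simulation study
#'
#' Describes the factorial design: topologies x time-series lengths x
#' estimation methods x selection criteria, replicated over seeds. All
#' randomness is controlled by explicit seeds.
#'
#' @param topologies list of topology specifications; each a list with
#'   `type` (`"random"`, `"acquaintance"`, `"preferential"`) plus the
#'   generator's arguments (`n_nodes` and `count`/`probability`, `p_d` and
#'   `iterations`, or `m`) and optionally `name`.
#' @param lengths increasing vector of time-series lengths.
#' @param methods subset of `c("pairwise", "shrinkage", "pseudoinverse",
#'   "glasso")`.
#' @param criteria subset of `c("k_minus", "k_true", "k_plus")` (true
#'   density and +/- 20%).
#' @param seeds integer vector of replicate seeds.
#' @param rho AR(1) autocorrelation of the simulated series.
#' @param variance common node variance of the generating covariance.
#' @param n_candidates candidate networks generated per topology before
#'   picking the representative one (1 skips the selection).
#' @param output_dir optional directory; when set, all artifacts and a
#'   manifest with content hashes are written there.
#' @return list of class `study_config`.
#' @export
study_config <- function(topologies, lengths, methods = c("pairwise",
                         "shrinkage", "pseudoinverse", "glasso"),
                         criteria = c("k_minus", "k_true", "k_plus"),
                         seeds = 1L, rho = 0.5, variance = 2,
                         n_candidates = 1L, output_dir = NULL) {
  stopifnot(is.list(topologies), length(topologies) > 0L)
  if (is.unsorted(lengths, strictly = TRUE))
    stop_invalid("`lengths` must be strictly increasing")
  methods <- match.arg(methods, c("pairwise", "shrinkage", "pseudoinverse",
                                  "glasso"), several.ok = TRUE)
  criteria <- match.arg(criteria, c("k_minus", "k_true", "k_plus"),
                        several.ok = TRUE)
  stopifnot(all(seeds == round(seeds)))
  structure(list(topologies = topologies, lengths = lengths,
                 methods = methods, criteria = criteria,
                 seeds = as.integer(seeds), rho = rho, variance = variance,
                 n_candidates = as.integer(n_candidates),
                 output_dir = output_dir),
            class = "study_config")
}

# deterministic sub-seed derivation, kept within 32-bit integer range
seed_stream <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483587 + 1)
}

generate_topology <- function(spec, seed) {
  gen <- switch(spec$type,
    random = function(s) {
      if (!is.null(spec$count))
        generate_random(spec$n_nodes, count = spec$count, seed = s)
      else generate_random(spec$n_nodes, probability = spec$probability,
                           seed = s)
    },
    acquaintance = function(s)
      generate_acquaintance(spec$n_nodes, spec$p_d, spec$iterations,
                            seed = s),
    preferential = function(s)
      generate_preferential(spec$n_nodes, spec$m, seed = s),
    stop_invalid("unknown topology type: ", spec$type))
  gen(seed)
}

#' Run the full simulation-and-recovery study
#'
#' For every design cell (topology x replicate seed x length x method x
#' selection criterion): generate the topology (optionally the
#' representative of several candidates), build a Gaussian graphical model
#' on it, simulate AR(1) time series, estimate weights, select edges at the
#' criterion's density, and score the result against the truth. Failures in
#' a cell are recorded and the run continues.
#'
#' @param config a [study_config()].
#' @param verbose print one line per stage.
#' @return list of class `study_result` with `summary` (tidy data frame:
#'   one row per cell with tpr, fpr, metric columns), `reports` (nested
#'   list of full `recovery_report`s), `truths` and `errors`.
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  rows <- list()
  reports <- list()
  truths <- list()
  errors <- list()
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  for (ti in seq_along(config$topologies)) {
    spec <- config$topologies[[ti]]
    tname <- if (!is.null(spec$name)) spec$name else
      paste0(spec$type, ti)
    for (rep_seed in config$seeds) {
      say("[%s seed %d] generating topology", tname, rep_seed)
      topo <- tryCatch({
        if (config$n_candidates > 1L) {
          cands <- lapply(seq_len(config$n_candidates), function(c_i)
            finalize_connected(
              generate_topology(spec, seed_stream(rep_seed, ti * 100 + c_i))))
          mets <- lapply(cands, topology_metrics)
          cands[[select_representative(mets)]]
        } else {
          finalize_connected(
            generate_topology(spec, seed_stream(rep_seed, ti * 100)))
        }
      }, error = function(e) e)
      cell_id <- paste(tname, rep_seed, sep = ".")
      if (inherits(topo, "error")) {
        errors[[cell_id]] <- conditionMessage(topo)
        next
      }
      truths[[cell_id]] <- topo
      k_true <- n_edges(topo)
      ks <- density_variants(k_true)
      bins <- assign_degree_bins(topo,
                                 top_n = min(50L, max(1L,
                                                      topo$n_nodes %/% 4L)))
      say("[%s seed %d] building GGM (p=%d, k=%d)", tname, rep_seed,
          topo$n_nodes, k_true)
      ggm <- build_ggm(topo, seed = seed_stream(rep_seed, ti * 100 + 31),
                       variance = config$variance)
      ts_full <- simulate_ar1_gaussian(ggm$sigma, max(config$lengths),
                                       rho = config$rho,
                                       seed = seed_stream(rep_seed,
                                                          ti * 100 + 57))
      subsets <- nested_subsets(ts_full, config$lengths)
      if (!is.null(out_dir)) {
        write_edge_list(topo, file.path(out_dir,
                                        paste0(cell_id, "_truth.tsv")))
        write_matrix_csv(ggm$pcor, file.path(out_dir,
                                             paste0(cell_id, "_pcor.csv")))
      }
      for (li in seq_along(config$lengths)) {
        n_obs <- config$lengths[li]
        for (method in config$methods) {
          wcell <- paste(cell_id, n_obs, method, sep = ".")
          say("[%s] estimating", wcell)
          w <- tryCatch(
            estimate_weights(subsets[[li]], method,
                             target_edges = glasso_support_target(
                               max(ks[config$criteria]), topo$n_nodes)),
            error = function(e) e)
          if (inherits(w, "error")) {
            errors[[wcell]] <- conditionMessage(w)
            next
          }
          for (crit in config$criteria) {
            ccell <- paste(wcell, crit, sep = ".")
            rep_out <- tryCatch({
              net <- select_top_k(w, ks[[crit]])
              recovery_report(net, topo, bins = bins, weights = w)
            }, error = function(e) e)
            if (inherits(rep_out, "error")) {
              errors[[ccell]] <- conditionMessage(rep_out)
              next
            }
            reports[[ccell]] <- rep_out
            rows[[ccell]] <- data.frame(
              topology = tname, seed = rep_seed, n_obs = n_obs,
              method = method, criterion = crit, k = ks[[crit]],
              tpr = rep_out$tpr, fpr = rep_out$fpr,
              n_components = rep_out$metrics_estimated$n_components,
              small_worldness = rep_out$metrics_estimated$small_worldness,
              global_clustering =
                rep_out$metrics_estimated$global_clustering,
              avg_path_length = rep_out$metrics_estimated$avg_path_length,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  summary_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame()
  rownames(summary_df) <- NULL
  result <- structure(list(summary = summary_df, reports = reports,
                           truths = truths, errors = errors,
                           config = config),
                      class = "study_result")
  if (!is.null(out_dir)) {
    utils::write.table(summary_df, file.path(out_dir, "summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    files <- setdiff(list.files(out_dir, full.names = TRUE),
                     file.path(out_dir, "manifest.json"))
    manifest <- list(files = as.list(tools::md5sum(files)))
    write_report_json(manifest, file.path(out_dir, "manifest.json"))
  }
  result
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d cells, %d errors\n",
              nrow(x$summary), length(x$errors)))
  invisible(x)
}

# --- hierarchical ROI fixture -----------------------------------------------

#' Specification of a synthetic hierarchically parcellated recording
#'
#' Emulates a multi-resolution cortical parcellation: a fixed set of fine
#' ROIs is grouped into progressively coarser areas, each level refining
#' the next coarser one.
#'
#' @param sizes increasing vector of parcellation sizes (defaults to the
#'   common 68/114/219/448/1000 hierarchy).
#' @param T_len number of time points (volumes), default 240.
#' @param rho AR(1) autocorrelation, default 0.5.
#' @param density edge density of the generating network at the finest
#'   level, default 0.03.
#' @return list of class `roi_fixture_spec`.
#' @export
roi_fixture_spec <- function(sizes = c(68L, 114L, 219L, 448L, 1000L),
                             T_len = 240L, rho = 0.5, density = 0.03) {
  if (is.unsorted(sizes, strictly = TRUE))
    stop_invalid("`sizes` must be strictly increasing")
  structure(list(sizes = as.integer(sizes), T_len = as.integer(T_len),
                 rho = rho, density = density),
            class = "roi_fixture_spec")
}

# nested contiguous-block partitions of `fine_p` items into each size in
# `sizes` (ascending); returns list of assignments (finest node -> area)
nested_partition <- function(fine_p, sizes) {
  stopifnot(max(sizes) == fine_p)
  assignments <- vector("list", length(sizes))
  names(assignments) <- as.character(sizes)
  # finest level: identity
  assignments[[length(sizes)]] <- seq_len(fine_p)
  # coarser levels by merging contiguous runs of the next finer level
  for (li in rev(seq_len(length(sizes) - 1L))) {
    finer <- assignments[[li + 1L]]
    n_fine_areas <- sizes[li + 1L]
    n_coarse <- sizes[li]
    base <- n_fine_areas %/% n_coarse
    extra <- n_fine_areas %% n_coarse
    sizes_blocks <- rep(base, n_coarse) +
      c(rep(1L, extra), rep(0L, n_coarse - extra))
    area_of_finer <- rep(seq_len(n_coarse), times = sizes_blocks)
    assignments[[li]] <- area_of_finer[finer]
  }
  assignments
}

#' Generate a synthetic hierarchical ROI time-series bundle
#'
#' Stand-in for a parcellated resting-state recording (the fixture is fully
#' synthetic): a sparse Gaussian graphical model is built on the finest
#' parcellation, AR(1) time series are simulated, and each coarser level's
#' series are the means of their constituent fine ROIs.
#'
#' @param spec a [roi_fixture_spec()].
#' @param seed integer RNG seed.
#' @return list of class `roi_bundle` with `series` (list of ROI x T
#'   matrices, one per level, named by size), `assignments` (per level,
#'   area index of every finest ROI), `truth` (finest-level
#'   `network_topology`) and `spec`.
#' @export
generate_roi_fixture <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "roi_fixture_spec"))
  fine_p <- max(spec$sizes)
  assignments <- nested_partition(fine_p, spec$sizes)
  k <- fixed_density_k(fine_p, spec$density)
  topo <- finalize_connected(
    generate_random(fine_p, count = k, seed = seed_stream(seed, 1L)))
  if (topo$n_nodes < fine_p) {
    # keep the full node set: reattach dropped nodes with one random edge
    # each so the fixture always has exactly `fine_p` ROIs
    g <- generate_random(fine_p, count = k, seed = seed_stream(seed, 1L))
    comp <- igraph::components(as_igraph(g))
    main <- which.max(comp$csize)
    stray <- which(comp$membership != main)
    anchors <- with_seed(seed_stream(seed, 2L),
                         sample(which(comp$membership == main),
                                length(stray), replace = TRUE))
    topo <- network_topology(fine_p, rbind(g$edges, cbind(stray, anchors)))
  }
  ggm <- build_ggm(topo, seed = seed_stream(seed, 3L))
  ts_fine <- simulate_ar1_gaussian(ggm$sigma, spec$T_len, rho = spec$rho,
                                   seed = seed_stream(seed, 4L))
  series <- lapply(seq_along(spec$sizes), function(li) {
    a <- assignments[[li]]
    agg <- rowsum(ts_values(ts_fine), group = a) /
      as.vector(table(a))
    structure(as.matrix(agg), rho = spec$rho,
              class = c("time_series_matrix", "matrix", "array"))
  })
  names(series) <- as.character(spec$sizes)
  structure(list(series = series, assignments = assignments, truth = topo,
                 ggm = ggm, spec = spec, seed = as.integer(seed)),
            class = "roi_bundle")
}

# mapping of level `fine_li` areas to level `coarse_li` areas
level_mapping <- function(bundle, fine_li, coarse_li) {
  stopifnot(coarse_li < fine_li)
  af <- bundle$assignments[[fine_li]]
  ac <- bundle$assignments[[coarse_li]]
  vapply(seq_len(max(af)), function(a) ac[match(a, af)], integer(1))
}

#' Default near-geometric grid of prefix lengths
#'
#' @param T_len full series length.
#' @param n_lengths number of prefixes (default 16).
#' @param min_len shortest prefix (default 15).
#' @return decreasing integer vector starting at `T_len`.
#' @export
prefix_lengths <- function(T_len, n_lengths = 16L, min_len = 15L) {
  stopifnot(T_len >= min_len)
  lens <- round(exp(seq(log(T_len), log(min_len), length.out = n_lengths)))
  sort(unique(as.integer(lens)), decreasing = TRUE)
}

#' Consistency of estimated networks across resolutions and lengths
#'
#' For each parcellation level and each prefix length: estimate the
#' network, keep the `density` strongest weights, and measure (a) the
#' overlap between the two methods' networks, (b) each method's overlap
#' with its own full-length reference network, and (c) at full length, the
#' within/between-area connectivity of each finer level against the
#' coarsest level.
#'
#' @param bundle a `roi_bundle` from [generate_roi_fixture()] (or a
#'   compatible list of ROI x T matrices plus assignments).
#' @param methods estimator tags; default pairwise and shrinkage.
#' @param lengths prefix lengths; default [prefix_lengths()] of the full
#'   series. Prefixes shorter than 3 time points are skipped with a
#'   warning.
#' @param density selection density (default 0.03).
#' @return list with tidy data frames `length_overlap` (level, method,
#'   length, overlap with the full-length reference), `method_overlap`
#'   (level, length, overlap between the first two methods) and `area`
#'   (level, method, within, between vs the coarsest level).
#' @export
consistency_analysis <- function(bundle, methods = c("pairwise",
                                 "shrinkage"), lengths = NULL,
                                 density = 0.03) {
  series <- bundle$series
  sizes <- vapply(series, nrow, integer(1))
  T_len <- ncol(series[[1L]])
  if (is.null(lengths)) lengths <- prefix_lengths(T_len)
  bad <- lengths < 3L
  if (any(bad)) {
    warning("skipping prefix lengths < 3: ",
            paste(lengths[bad], collapse = ", "))
    lengths <- lengths[!bad]
  }
  nets <- list()  # [[level]][[method]][[as.character(length)]]
  for (li in seq_along(series)) {
    p <- sizes[li]
    k <- fixed_density_k(p, density)
    nets[[li]] <- lapply(methods, function(m) {
      out <- list()
      for (L in lengths) {
        ts_sub <- nested_subsets(series[[li]], L)[[1L]]
        out[[as.character(L)]] <- select_top_k(
          estimate_weights(ts_sub, m, target_edges = k), k)
      }
      out
    })
    names(nets[[li]]) <- methods
  }

  len_rows <- list(); meth_rows <- list(); area_rows <- list()
  full <- as.character(max(lengths))
  for (li in seq_along(series)) {
    for (m in methods) {
      ref <- nets[[li]][[m]][[full]]
      for (L in lengths) {
        len_rows[[length(len_rows) + 1L]] <- data.frame(
          level = sizes[li], method = m, length = L,
          overlap = edge_overlap(nets[[li]][[m]][[as.character(L)]], ref))
      }
    }
    if (length(methods) >= 2L) {
      for (L in lengths) {
        meth_rows[[length(meth_rows) + 1L]] <- data.frame(
          level = sizes[li], length = L,
          overlap = edge_overlap(
            nets[[li]][[methods[1L]]][[as.character(L)]],
            nets[[li]][[methods[2L]]][[as.character(L)]]))
      }
    }
    if (li > 1L) {
      mapping <- level_mapping(bundle, li, 1L)
      for (m in methods) {
        ac <- area_connectivity(nets[[1L]][[m]][[full]],
                                nets[[li]][[m]][[full]], mapping)
        area_rows[[length(area_rows) + 1L]] <- data.frame(
          level = sizes[li], method = m, within = ac$within,
          between = ac$between)
      }
    }
  }
  list(length_overlap = do.call(rbind, len_rows),
       method_overlap = if (length(meth_rows)) do.call(rbind, meth_rows)
         else NULL,
       area = if (length(area_rows)) do.call(rbind, area_rows) else NULL)
}
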