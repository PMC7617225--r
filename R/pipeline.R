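# End-to-end orchestration: synth -> segment -> glcm / vaegan -> cluster
# -> profile -> compare, with JSON provenance and config-hash caching.
#
# Every stage writes its outputs plus a "<stage>_provenance.json" sidecar
# recording the config hash, the stage seed and the files written. A
# stage whose provenance matches the current config is skipped unless
# force = TRUE (VAE-GAN training is the only slow stage and must be
# skippable). All stage seeds are derived deterministically from the
# global seed.

#' Assemble a pipeline configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed; every stochastic stage derives its own seed
#'   from it.
#' @param regions List of region entries, each a list with
#'   \code{region_id}, \code{condition} (\code{"CONTROL"} /
#'   \code{"TREATED"}), and optional \code{synth} overrides for
#'   \code{\link{synth_spec}}.
#' @param segment,glcm,vaegan,cluster,profile,compare Per-stage options;
#'   see Details.
#' @details Stage options (all optional): \code{segment}:
#'   \code{min_overlap_frac} (0.5), \code{cd8_dilate} (2),
#'   \code{gh2ax_threshold} / \code{cd8_threshold} ("otsu" or a number).
#'   \code{glcm}: arguments of \code{\link{glcm_config}}. \code{vaegan}:
#'   \code{enabled} (FALSE), plus \code{\link{vaegan_spec}} and
#'   \code{\link{train_config}} fields. \code{cluster}: \code{k} (5),
#'   \code{representation} ("GLCM" or "VAEGAN"). \code{profile}:
#'   \code{radii_px} (c(32, 64, 128)). \code{compare}: \code{n_perm}
#'   (999).
#' @return A \code{PipelineConfig} list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, regions,
                            segment = list(), glcm = list(),
                            vaegan = list(), cluster = list(),
                            profile = list(), compare = list()) {
  stopifnot(length(regions) >= 1)
  for (rg in regions)
    if (is.null(rg$region_id) || is.null(rg$condition))
      stop("each region needs region_id and condition")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 regions = regions, segment = segment, glcm = glcm,
                 vaegan = vaegan, cluster = cluster, profile = profile,
                 compare = compare),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of \code{\link{pipeline_config}}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

.stage_seed <- function(seed, stage, i = 0L) {
  off <- c(synth = 10000L, segment = 20000L, glcm = 30000L,
           vaegan = 40000L, cluster = 50000L, profile = 60000L,
           compare = 70000L)
  (seed + off[[stage]] + i) %% .Machine$integer.max
}

.prov_path <- function(dir, stage) file.path(dir,
  paste0(stage, "_provenance.json"))

.stage_done <- function(dir, stage, hash, outputs) {
  p <- .prov_path(dir, stage)
  if (!file.exists(p)) return(FALSE)
  prov <- tryCatch(jsonlite::read_json(p), error = function(e) NULL)
  !is.null(prov) && identical(prov$config_hash, hash) &&
    all(file.exists(outputs))
}

.write_prov <- function(dir, stage, hash, seed, outputs) {
  jsonlite::write_json(
    list(stage = stage, config_hash = hash, seed = seed,
         package_version = as.character(utils::packageVersion("h2axprofiler")),
         timestamp = format(Sys.time(), tz = "UTC"),
         outputs = outputs,
         output_md5 = as.list(tools::md5sum(outputs[file.exists(outputs)]))),
    .prov_path(dir, stage), auto_unbox = TRUE, force = TRUE)
}

.need <- function(files, stage_hint) {
  miss <- files[!file.exists(files)]
  if (length(miss))
    stop("missing upstream artifact(s): ", paste(miss, collapse = ", "),
         " - run the '", stage_hint, "' stage first")
  invisible(TRUE)
}

.log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the profiling pipeline
#'
#' Executes the requested stages in dependency order. Regions are
#' synthesized (or must already exist under \code{out_dir}), cells are
#' segmented and patched, texture features are computed, representations
#' are pooled and clustered into pseudo classes, neighborhoods are
#' profiled per region, and conditions compared. All outputs are CSV /
#' TIFF with JSON provenance.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param stages Character subset of \code{synth}, \code{segment},
#'   \code{glcm}, \code{vaegan}, \code{cluster}, \code{profile},
#'   \code{compare}.
#' @param force Re-run stages even when their provenance is up to date.
#' @return Invisibly, a list with \code{out_dir} and the per-stage status
#'   (\code{"ran"} / \code{"cached"} / \code{"skipped"}).
#' @export
run_pipeline <- function(config,
                         stages = c("synth", "segment", "glcm", "vaegan",
                                    "cluster", "profile", "compare"),
                         force = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  stages <- match.arg(stages, several.ok = TRUE)
  if (!isTRUE(config$vaegan$enabled)) stages <- setdiff(stages, "vaegan")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  status <- list()
  rdir <- function(rg) {
    d <- file.path(config$out_dir, rg$region_id)
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    d
  }
  t0 <- proc.time()[3]

  if ("synth" %in% stages) {
    for (i in seq_along(config$regions)) {
      rg <- config$regions[[i]]
      d <- rdir(rg)
      outs <- file.path(d, c("channels.tif", "labels.tif", "truth.csv"))
      if (!force && .stage_done(d, "synth", hash, outs)) {
        status[[paste0("synth:", rg$region_id)]] <- "cached"; next
      }
      sargs <- rg$synth
      sargs$rng_seed <- .stage_seed(config$seed, "synth", i)
      spec <- do.call(synth_spec, sargs)
      reg <- generate_region(spec)
      write_volume(reg$channels, outs[1])
      write_labels(reg$labels, outs[2])
      utils::write.csv(reg$truth, outs[3], row.names = FALSE)
      .write_prov(d, "synth", hash, sargs$rng_seed, outs)
      status[[paste0("synth:", rg$region_id)]] <- "ran"
      .log_stage("synth", sprintf("%s: %d nuclei (%.1fs)", rg$region_id,
                                  spec$n_nuclei, proc.time()[3] - t0))
    }
  }

  seg_opt <- function(o, d) if (is.null(o)) d else o
  if ("segment" %in% stages) {
    for (rg in config$regions) {
      d <- rdir(rg)
      ins <- file.path(d, c("channels.tif", "labels.tif"))
      outs <- file.path(d, c("cells.csv", "patches.csv"))
      if (!force && .stage_done(d, "segment", hash, outs)) {
        status[[paste0("segment:", rg$region_id)]] <- "cached"; next
      }
      .need(ins, "synth")
      chn <- c("DAPI", "GH2AX", "CD8")
      gh <- read_volume(ins[1], "GH2AX", channels = chn)
      cd <- read_volume(ins[1], "CD8", channels = chn)
      labs <- read_labels(ins[2])
      sg <- config$segment
      thr <- function(ch, opt) {
        if (is.numeric(opt)) threshold_channel(ch, "fixed", opt)
        else threshold_channel(ch, "otsu")
      }
      cells <- build_cell_table(
        labs, thr(gh, sg$gh2ax_threshold), thr(cd, sg$cd8_threshold),
        min_overlap_frac = seg_opt(sg$min_overlap_frac, 0.5),
        cd8_dilate = seg_opt(sg$cd8_dilate, 2L),
        condition = rg$condition, region_id = rg$region_id,
        voxel_size_um = gh$voxel_size_um)
      write_table(cells, outs[1])
      bank <- extract_patches(gh, cells, labs)
      if (length(bank)) write_patch_bank(bank, outs[2])
      else utils::write.csv(data.frame(cell_id = character(0)), outs[2],
                            row.names = FALSE)
      .write_prov(d, "segment", hash, config$seed, outs)
      status[[paste0("segment:", rg$region_id)]] <- "ran"
      .log_stage("segment", sprintf("%s: %d gamma-H2AX+ patches",
                                    rg$region_id, length(bank)))
    }
  }

  if ("glcm" %in% stages) {
    for (rg in config$regions) {
      d <- rdir(rg)
      ins <- file.path(d, "patches.csv")
      outs <- file.path(d, "glcm.csv")
      if (!force && .stage_done(d, "glcm", hash, outs)) {
        status[[paste0("glcm:", rg$region_id)]] <- "cached"; next
      }
      .need(ins, "segment")
      bank <- read_patch_bank(ins)
      cfg <- do.call(glcm_config, config$glcm)
      ft <- glcm_table(bank, cfg)
      write_table(ft, outs)
      .write_prov(d, "glcm", hash, config$seed, outs)
      status[[paste0("glcm:", rg$region_id)]] <- "ran"
    }
  }

  if ("vaegan" %in% stages) {
    outs <- file.path(config$out_dir,
                      c("vaegan_loss_history.csv", "vaegan_model.rds"))
    if (!force && .stage_done(config$out_dir, "vaegan", hash, outs)) {
      status[["vaegan"]] <- "cached"
    } else {
      banks <- list()
      for (rg in config$regions) {
        p <- file.path(rdir(rg), "patches.csv")
        .need(p, "segment")
        b <- read_patch_bank(p)
        names(b) <- paste0(rg$region_id, ":", names(b))
        banks <- c(banks, b)
      }
      vg <- config$vaegan
      spec <- vaegan_spec(
        latent_dim = seg_opt(vg$latent_dim, 16L),
        width_base = seg_opt(vg$width_base, 16L))
      sd_ <- .stage_seed(config$seed, "vaegan")
      model <- build_vaegan(spec, seed = sd_)
      tc <- train_config(
        epochs = seg_opt(vg$epochs, 20L),
        batch_size = seg_opt(vg$batch_size, 32L),
        learning_rate = seg_opt(vg$learning_rate, 1e-4),
        seed = sd_, augment = seg_opt(vg$augment, TRUE))
      tr <- train_vaegan(model, banks, tc)
      utils::write.csv(tr$history, outs[1], row.names = FALSE)
      saveRDS(tr$model, outs[2])
      lt <- encode_table(tr$model, banks)
      split_ids <- strsplit(lt$cell_id, ":", fixed = TRUE)
      for (rg in config$regions) {
        sel <- vapply(split_ids, `[`, character(1), 1) == rg$region_id
        sub <- lt[sel, , drop = FALSE]
        sub$cell_id <- vapply(split_ids[sel], `[`, character(1), 2)
        write_table(sub, file.path(rdir(rg), "latent.csv"))
      }
      .write_prov(config$out_dir, "vaegan", hash, sd_, outs)
      status[["vaegan"]] <- "ran"
      .log_stage("vaegan", sprintf("trained %d epochs on %d patches",
                                   tc$epochs, length(banks)))
    }
  }

  rep_src <- toupper(seg_opt(config$cluster$representation, "GLCM"))
  feat_file <- if (rep_src == "VAEGAN") "latent.csv" else "glcm.csv"
  if ("cluster" %in% stages) {
    outs <- file.path(config$out_dir, "classes.csv")
    if (!force && .stage_done(config$out_dir, "cluster", hash, outs)) {
      status[["cluster"]] <- "cached"
    } else {
      feats <- list()
      for (rg in config$regions) {
        p <- file.path(rdir(rg), feat_file)
        .need(p, if (rep_src == "VAEGAN") "vaegan" else "glcm")
        f <- read_table_csv(p)
        f$cell_id <- paste0(rg$region_id, ":", f$cell_id)
        feats[[rg$region_id]] <- f
      }
      pooled <- do.call(rbind, feats)
      if (rep_src == "VAEGAN") class(pooled) <- c("LatentTable",
                                                  "data.frame")
      k <- seg_opt(config$cluster$k, 5L)
      cls <- cluster_representations(
        pooled, k = k, seed = .stage_seed(config$seed, "cluster"))
      attr(cls, "meta") <- list(k = k, representation = rep_src,
                                inertia = attr(cls, "inertia"))
      write_table(cls, outs)
      .write_prov(config$out_dir, "cluster", hash,
                  .stage_seed(config$seed, "cluster"), outs)
      status[["cluster"]] <- "ran"
      .log_stage("cluster", sprintf("%d cells into %d pseudo classes (%s)",
                                    nrow(cls), k, rep_src))
    }
  }

  radii <- seg_opt(config$profile$radii_px, c(32, 64, 128))
  if ("profile" %in% stages) {
    cls_file <- file.path(config$out_dir, "classes.csv")
    for (rg in config$regions) {
      d <- rdir(rg)
      outs <- c(file.path(d, "profiles.csv"), file.path(d, "cd8_report.csv"),
                file.path(d, sprintf("heatmap_r%g.csv", radii)))
      if (!force && .stage_done(d, "profile", hash, outs)) {
        status[[paste0("profile:", rg$region_id)]] <- "cached"; next
      }
      .need(file.path(d, "cells.csv"), "segment")
      .need(cls_file, "cluster")
      cells <- read_table_csv(file.path(d, "cells.csv"))
      cls <- read_table_csv(cls_file)
      k <- attr(cls, "k")
      pref <- paste0(rg$region_id, ":")
      mine <- startsWith(cls$cell_id, pref)
      cls_r <- cls[mine, , drop = FALSE]
      cls_r$cell_id <- as.integer(sub(pref, "", cls_r$cell_id,
                                      fixed = TRUE))
      attr(cls_r, "k") <- as.integer(k)
      # positives whose patch was skipped (degenerate bbox) have no class;
      # they cannot serve as centers or class-neighbors
      unlab <- cells$gh2ax_pos & !(cells$cell_id %in% cls_r$cell_id)
      if (any(unlab)) {
        .log_stage("profile", sprintf("%s: dropping %d unpatched positives",
                                      rg$region_id, sum(unlab)))
        cells$gh2ax_pos[unlab] <- FALSE
      }
      profs <- list()
      for (ri in seq_along(radii)) {
        pr <- neighborhood_counts(cells, cls_r, radii[ri],
                                  attr(cells, "voxel_size_um"))
        profs[[ri]] <- pr
        hm <- cooccurrence_heatmap(pr, k = attr(pr, "k"),
                                   condition = attr(cells, "condition"))
        utils::write.csv(as.data.frame(hm$H), outs[2 + ri],
                         row.names = TRUE)
      }
      all_pr <- do.call(rbind, profs)
      attr(all_pr, "condition") <- attr(cells, "condition")
      attr(all_pr, "region_id") <- rg$region_id
      write_table(all_pr, outs[1])
      rep_ <- cd8_proximity_report(cells, radii,
                                   attr(cells, "voxel_size_um"))
      summ <- rep_$summary
      attr(summ, "condition") <- attr(cells, "condition")
      attr(summ, "region_id") <- rg$region_id
      write_table(summ, outs[2])
      .write_prov(d, "profile", hash, config$seed, outs)
      status[[paste0("profile:", rg$region_id)]] <- "ran"
    }
  }

  if ("compare" %in% stages) {
    conds <- vapply(config$regions, `[[`, character(1), "condition")
    if (!all(c("CONTROL", "TREATED") %in% conds)) {
      status[["compare"]] <- "skipped"
    } else {
      outs <- file.path(config$out_dir,
                        c("compare_heatmaps.csv", "compare_proximity.csv"))
      if (!force && .stage_done(config$out_dir, "compare", hash, outs)) {
        status[["compare"]] <- "cached"
      } else {
        hms <- list(); reps <- list()
        for (rg in config$regions) {
          d <- rdir(rg)
          .need(file.path(d, "profiles.csv"), "profile")
          prof <- read_table_csv(file.path(d, "profiles.csv"))
          kk <- length(grep("^n_class_", names(prof)))
          for (r in radii) {
            sub <- prof[prof$radius_px == r, , drop = FALSE]
            attr(sub, "k") <- kk
            hms[[length(hms) + 1L]] <-
              cooccurrence_heatmap(sub, k = kk,
                                   condition = rg$condition)
          }
          summ <- read_table_csv(file.path(d, "cd8_report.csv"))
          reps[[length(reps) + 1L]] <-
            structure(list(summary = summ, condition = rg$condition),
                      class = "ProximityReport")
        }
        cmp <- compare_conditions(hms, reps,
                                  n_perm = seg_opt(config$compare$n_perm,
                                                   999L),
                                  seed = .stage_seed(config$seed,
                                                     "compare"))
        utils::write.csv(cmp$heatmap_diff, outs[1], row.names = FALSE)
        utils::write.csv(cmp$proximity_diff, outs[2], row.names = FALSE)
        .write_prov(config$out_dir, "compare", hash,
                    .stage_seed(config$seed, "compare"), outs)
        status[["compare"]] <- "ran"
      }
    }
  }

  invisible(list(out_dir = config$out_dir, status = status,
                 config_hash = hash))
}
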