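#' Configuration for an end-to-end run
#'
#' Collects every tunable of the pipeline with the protocol defaults:
#' 100 x 100 template, 100 hidden units, learning rate 0.1, 10,000 training
#' epochs, CD-1, 10,000 Gibbs sweeps keeping 5,000, 8 Angstrom cutoff,
#' separation filter 4, template exponent 2, pseudocount 0.5, reweighting
#' identity 0.8, 50% row gap filter, top 100 predictions. Inputs may be
#' in-memory objects or file paths (dense-matrix TSV for maps/distances,
#' FASTA/Stockholm for the alignment, dot-bracket text for the structure).
#'
#' @param training_maps list of distance matrices and/or binary contact maps
#'   (template-size maps are used as-is; distance matrices are resized then
#'   thresholded), or a directory of `*.tsv` dense matrices.
#' @param msa `msa` object or alignment path.
#' @param native_map optional native contact map / distance matrix (or path)
#'   for evaluation.
#' @param ss optional `secondary_structure` or dot-bracket string/path.
#' @param exclusion_list identifiers (names in `training_maps`) to drop as
#'   homologs of the target.
#' @param target_id identifier of the target (leakage warning when present in
#'   the training set with no exclusion list).
#' @param template_size,n_hidden,learning_rate,epochs,cd_k,n_total,n_keep,cutoff,min_separation,exponent,pseudocount,reweight_threshold,max_gap_fraction,top_n,seed protocol parameters.
#' @return a `direct_config` list.
#' @export
direct_config <- function(training_maps, msa, native_map = NULL, ss = NULL,
                          exclusion_list = character(0), target_id = NULL,
                          template_size = 100L, n_hidden = 100L,
                          learning_rate = 0.1, epochs = 10000L, cd_k = 1L,
                          n_total = 10000L, n_keep = 5000L, cutoff = 8.0,
                          min_separation = 4L, exponent = 2L,
                          pseudocount = 0.5, reweight_threshold = 0.8,
                          max_gap_fraction = 0.5, top_n = 100L, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cutoff > 0, min_separation >= 0, exponent >= 1, exponent <= 4,
            pseudocount >= 0, pseudocount < 1,
            reweight_threshold > 0, reweight_threshold <= 1,
            max_gap_fraction >= 0, max_gap_fraction <= 1,
            n_keep <= n_total, epochs >= 1, n_hidden >= 1)
  structure(cfg, class = "direct_config")
}

#' Remove homologs of the target from the training set
#'
#' Homology detection is delegated to the caller: maps whose names appear in
#' `exclusion_list` are dropped. If the target itself is present in the
#' training set and no exclusion list is given, a train/test-leakage warning
#' is raised.
#'
#' @param training_maps named list of training maps.
#' @param target_id identifier of the prediction target.
#' @param exclusion_list identifiers to remove.
#' @return the filtered list.
#' @export
exclude_homologs <- function(training_maps, target_id = NULL,
                             exclusion_list = character(0)) {
  nms <- names(training_maps)
  if (length(exclusion_list) == 0L) {
    if (!is.null(target_id) && !is.null(nms) && target_id %in% nms) {
      warning("possible train/test leakage: target '", target_id,
              "' is in the training set and no exclusion list was given",
              call. = FALSE)
    }
    return(training_maps)
  }
  if (is.null(nms)) return(training_maps)
  kept <- training_maps[!(nms %in% exclusion_list)]
  message("excluded ", length(training_maps) - length(kept),
          " homologous training map(s)")
  kept
}

load_map_input <- function(x) {
  if (is.character(x) && length(x) == 1L) read_matrix_tsv(x) else as.matrix(x)
}

# distance matrices (any entry > 1, non-binary) vs binary contact maps
is_binary_map <- function(m) all(m %in% c(0, 1))

#' Run the full contact-prediction pipeline
#'
#' Executes the workflow end to end: (1) training maps are brought to the
#' template size (distance matrices resized by bilinear interpolation, then
#' thresholded at the cutoff with no separation filter) and flattened;
#' (2) the template machine is trained by contrastive divergence; (3) Gibbs
#' sampling yields the contact-frequency template; (4) mean-field coupling
#' analysis of the alignment yields the DI matrix; (5) the projected template
#' reweights DI (`DI * W^exponent`) and contacts are ranked; (6) when a native
#' map is supplied, the prediction is evaluated. A manifest records the
#' effective parameters, seeds, stage timings and input hashes.
#'
#' @param config a `direct_config`.
#' @return a `direct_run`: list with `contacts`, `contacts_di` (unweighted
#'   ranking), `report`, `report_di`, `template`, `di`, `model`, `manifest`.
#' @export
run_direct <- function(config) {
  stopifnot(inherits(config, "direct_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  # --- stage: training maps -------------------------------------------------
  tm <- config$training_maps
  if (is.character(tm) && length(tm) == 1L && dir.exists(tm)) {
    files <- sort(list.files(tm, pattern = "\\.tsv$", full.names = TRUE))
    tm <- setNames(lapply(files, read_matrix_tsv),
                   tools::file_path_sans_ext(basename(files)))
  }
  tm <- exclude_homologs(tm, config$target_id, config$exclusion_list)
  if (length(tm) == 0L) pipeline_fail("training", "no training maps left")
  M <- config$template_size
  vectors <- lapply(tm, function(x) {
    m <- load_map_input(x)
    if (is_binary_map(m)) {
      if (nrow(m) != M) {
        pipeline_fail("training", "binary training map is not template-sized; supply distance matrices for resizing")
      }
      flatten_map(m)
    } else {
      flatten_map(contact_map(resize_distance_matrix(m, M),
                              cutoff = config$cutoff, min_separation = 0L))
    }
  })
  tick("prepare_training")

  # --- stage: template machine ---------------------------------------------
  model <- train_rbm(vectors, n_hidden = config$n_hidden,
                     learning_rate = config$learning_rate,
                     epochs = config$epochs, cd_k = config$cd_k,
                     seed = config$seed)
  tick("train_rbm")
  samples <- gibbs_sample(model, n_total = config$n_total,
                          n_keep = config$n_keep,
                          seed = child_seed(config$seed, 2L))
  template <- contact_weight(samples, template_size = M)
  tick("gibbs_sample")

  # --- stage: coupling analysis --------------------------------------------
  aln <- if (inherits(config$msa, "msa")) config$msa else read_msa(config$msa)
  dres <- tryCatch(
    dca(aln, pseudocount = config$pseudocount,
        reweight_threshold = config$reweight_threshold,
        max_gap_fraction = config$max_gap_fraction),
    error = function(e) pipeline_fail("dca", conditionMessage(e)))
  L <- nrow(dres$di)
  tick("dca")

  # --- stage: reweight + rank ----------------------------------------------
  wp <- project_weight(template, L)
  scores <- direct_reweight(dres$di, wp, config$exponent)
  contacts <- rank_contacts(scores, config$min_separation, config$top_n,
                            scheme = "DIRECT")
  contacts_di <- rank_contacts(unclass(as.matrix(dres$di)),
                               config$min_separation, config$top_n,
                               scheme = "DI")
  tick("score")

  # --- stage: evaluation ----------------------------------------------------
  report <- report_di <- NULL
  ss <- config$ss
  if (!is.null(ss) && !inherits(ss, "secondary_structure")) {
    ss <- read_dotbracket(if (file.exists(ss)) readLines(ss, warn = FALSE) else ss)
  }
  if (!is.null(config$native_map)) {
    nm <- load_map_input(config$native_map)
    native <- if (is_binary_map(nm)) new_contact_map(nm, config$cutoff,
                                                     config$min_separation)
    else contact_map(nm, config$cutoff, config$min_separation)
    report <- contact_breakdown(contacts, native, ss = ss, n = config$top_n)
    report_di <- contact_breakdown(contacts_di, native, ss = ss,
                                   n = config$top_n)
  }
  tick("evaluate")

  manifest <- run_manifest(config, timings)
  structure(list(contacts = contacts, contacts_di = contacts_di,
                 report = report, report_di = report_di,
                 template = template, weight_projected = wp, di = dres$di,
                 model = model, manifest = manifest),
            class = "direct_run")
}

pipeline_fail <- function(stage, msg) {
  stop("pipeline stage '", stage, "' failed: ", msg, call. = FALSE)
}

run_manifest <- function(config, timings) {
  file_inputs <- Filter(function(x) is.character(x) && length(x) == 1L &&
                          file.exists(x) && !dir.exists(x),
                        config[c("training_maps", "msa", "native_map", "ss")])
  params <- config[!(names(config) %in%
                       c("training_maps", "msa", "native_map", "ss"))]
  list(parameters = params,
       input_hashes = if (length(file_inputs)) {
         h <- tools::md5sum(unlist(file_inputs))
         setNames(as.list(unname(h)), names(file_inputs))
       } else list(),
       stage_seconds = as.list(timings),
       r_version = as.character(getRversion()),
       package_version = as.character(utils::packageVersion("rnadirect")),
       timestamp = format(Sys.time(), tz = "UTC"))
}

#' @export
print.direct_run <- function(x, ...) {
  cat("<direct_run>", nrow(x$contacts), "ranked contacts\n")
  if (!is.null(x$report)) {
    cat(sprintf("  DIRECT PPV@%d %.3f | DI PPV@%d %.3f\n",
                x$report$n, x$report$ppv_at_n,
                x$report_di$n, x$report_di$ppv_at_n))
  }
  invisible(x)
}
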