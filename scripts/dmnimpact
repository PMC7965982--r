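#!/usr/bin/env Rscript

# Thin command-line front end over the dmnimpact package.
# Subcommands: make-fixtures, simulate-library, train, evaluate, predict,
#              invert-velocity, functional-damage, reconstruct

suppressPackageStartupMessages({
  library(dmnimpact)
  library(dplyr)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) == 0) {
  cat("usage: dmnimpact <subcommand> [--flag value ...]\n",
      "subcommands: make-fixtures simulate-library train evaluate predict",
      "invert-velocity functional-damage reconstruct\n")
  quit(status = 1)
}
cmd <- argv[1]
kv <- list()
i <- 2L
while (i <= length(argv)) {
  key <- sub("^--", "", argv[i])
  kv[[key]] <- argv[i + 1L]
  i <- i + 2L
}
opt <- function(name, default = NULL) {
  if (!is.null(kv[[name]])) kv[[name]] else default
}
num <- function(name, default = NULL) {
  v <- opt(name, default)
  if (is.null(v)) NULL else as.numeric(v)
}
seed <- as.integer(opt("seed", 0))

standard_setup <- function() {
  mesh <- build_toy_head_mesh(as.integer(opt("resolution", 3)), seed = seed)
  template <- default_dmn_template()
  ids <- map_dmn_elements(mesh, binarize_dmn_template(template))
  list(mesh = mesh, template = template, ids = ids)
}

emit <- function(x, path = opt("json")) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) writeLines(txt, path) else cat(txt, "\n")
}

if (cmd == "make-fixtures") {
  outdir <- opt("out", "fixtures")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  s <- standard_setup()
  write_mesh_vtk(s$mesh, file.path(outdir, "head_mesh.vtk"))
  write_volume_nifti(s$template, file.path(outdir, "dmn_template.nii.gz"))
  write_volume_nifti(binarize_dmn_template(s$template),
                     file.path(outdir, "dmn_mask.nii.gz"))
  emit(list(outdir = outdir, n_dmn_elements = length(s$ids)))

} else if (cmd == "simulate-library") {
  s <- standard_setup()
  lib <- build_scenario_library(scenario_grid(), s$mesh,
                                surrogate_params(seed = seed),
                                dmn_ids = s$ids)
  write_library_csv(lib, opt("out", "library.csv"))
  emit(list(records = nrow(lib), fractured = sum(lib$fractured),
            out = opt("out", "library.csv")))

} else if (cmd %in% c("train", "evaluate", "predict", "invert-velocity")) {
  s <- standard_setup()
  lib <- read_library_csv(opt("library", "library.csv"))
  lib_ok <- filter(lib, !fractured)
  th <- num("threshold", num("target-damage", 50))
  feats <- extract_features(lib_ok, s$mesh, s$ids)
  labels <- label_library(lib_ok, th)
  sel <- forward_feature_selection(feats, labels, seed = seed)
  ens <- train_bagging_ensemble(feats, labels, sel, damage_threshold = th,
                                seed = seed)
  if (cmd == "train") {
    dir <- opt("out", "ensemble")
    write_ensemble(ens, dir)
    emit(list(model = dir, threshold = th, features = ens$selected))
  } else if (cmd == "evaluate") {
    ev <- evaluate_loo(feats, labels, method = opt("method", "bagging"),
                       selected = sel, seed = seed)
    emit(as.list(ev$metrics))
  } else {
    sc <- impact_scenario(num("velocity", 8), opt("location", "vertex"),
                          num("angle", 0), opt("impactor", "round"))
    if (cmd == "predict") {
      f <- extract_features(sc, s$mesh, s$ids)
      emit(list(scenario = as.list(sc), threshold = th,
                probability = unname(predict(ens, f))))
    } else {
      cur <- probability_velocity_curve(ens, sc, s$mesh, s$ids)
      pl <- plateau_and_velocity(cur, smooth = TRUE)
      if (!is.null(opt("curve-out"))) {
        readr::write_csv(cur, opt("curve-out"))
      }
      emit(list(target_damage = th, P_f = pl$P_f, v_at_95 = pl$v_at_95,
                reached = pl$reached))
    }
  }

} else if (cmd == "functional-damage") {
  patient <- read_volume_nifti(opt("patient"))
  ctl_paths <- strsplit(opt("controls"), ",")[[1]]
  controls <- lapply(ctl_paths, read_volume_nifti)
  mask <- read_volume_nifti(opt("dmn-mask")) > 0.5
  res <- single_case_permutation(array(patient, dim(patient)),
                                 lapply(controls, function(x)
                                   array(x, dim(x))),
                                 n_perm = as.integer(opt("n-perm", 5000)),
                                 seed = seed)
  dl <- damage_load(res, mask, alpha = num("alpha", 0.05))
  if (!is.null(opt("p-out"))) {
    p <- res$p_map; attr(p, "affine") <- attr(patient, "affine")
    write_volume_nifti(p, opt("p-out"))
  }
  emit(as.list(dl))

} else if (cmd == "reconstruct") {
  rec <- reconstruct_case(opt("case"))
  emit(list(case = attr(rec, "case_id"),
            quantities = purrr::pmap(rec, list)))

} else {
  stop("unknown subcommand: ", cmd)
}
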