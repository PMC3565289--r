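# Dataset manifest and model-family serialization (versioned JSON / CSV).

#' Write a model family as a versioned JSON document
#'
#' Stores the envelope coordinates, every member's property string and
#' scenarios, the GA config and the training seed.
#'
#' @param family a [ModelFamily-class].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
writeModelFamily <- function(family, path) {
  doc <- list(
    format = "affinityprofiler-family", version = 1L,
    seed = family@seed, config = family@config,
    envelope = list(positions = round(family@envelope@positions, 6),
                    center = family@envelope@center,
                    spacing = family@envelope@spacing,
                    offset = family@envelope@offset),
    members = lapply(family@members, function(m) list(
      labels = paste(m@labels, collapse = ""),
      induced_fit_scenario = m@induced_fit_scenario,
      solvation_scenario = m@solvation_scenario,
      induced_fit_penalty = m@induced_fit_penalty,
      base_energy = m@base_energy)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model family written by [writeModelFamily()]
#' @param path JSON file.
#' @return A [ModelFamily-class].
#' @export
readModelFamily <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "affinityprofiler-family"))
    .afp_stop("not a model-family document", "afp_format_error")
  env <- new("Envelope", positions = as.matrix(doc$envelope$positions),
             center = as.numeric(doc$envelope$center),
             spacing = doc$envelope$spacing, offset = doc$envelope$offset)
  members <- lapply(seq_len(nrow(doc$members)), function(i) {
    m <- doc$members[i, ]
    surrogateModel(env,
                   as.integer(strsplit(m$labels, "")[[1]]),
                   m$induced_fit_scenario, m$solvation_scenario,
                   m$induced_fit_penalty, m$base_energy)
  })
  new("ModelFamily", envelope = env, members = members,
      config = as.list(doc$config), seed = as.integer(doc$seed))
}

#' Write a QSAR dataset as manifest + per-ligand pose files
#'
#' Emits `manifest.csv` (`ligand_id,pose_file,energy_file,charge_file,
#' exp_pic50,split`), one multi-model PDB per ligand, a per-pose
#' conformational-energy CSV and a sidecar charge CSV.
#'
#' @param dataset a [QsarDataset-class].
#' @param dir output directory (created).
#' @return path of the manifest, invisibly.
#' @export
writeQsarDataset <- function(dataset, dir) {
  dir.create(file.path(dir, "poses"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dataset@ids), function(i) {
    id <- dataset@ids[i]
    ens <- dataset@ensembles[[i]]
    pf <- file.path("poses", paste0(id, ".pdb"))
    ef <- file.path("poses", paste0(id, ".energies.csv"))
    cf <- file.path("poses", paste0(id, ".charges.csv"))
    topo <- ens@poses[[1]]
    writePDB(trajectory(topo, coords = lapply(ens@poses, coords)),
             file.path(dir, pf))
    utils::write.csv(data.frame(pose = seq_along(ens@conf_energies),
                                conf_energy = ens@conf_energies),
                     file.path(dir, ef), row.names = FALSE, quote = FALSE)
    writeChargeTable(topo, file.path(dir, cf))
    data.frame(ligand_id = id, pose_file = pf, energy_file = ef,
               charge_file = cf, exp_pic50 = dataset@pic50[i],
               split = as.character(dataset@split[i]))
  })
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), mf, row.names = FALSE, quote = FALSE)
  invisible(mf)
}

#' Read a QSAR dataset from a manifest written by [writeQsarDataset()]
#' @param manifest_path path to `manifest.csv`.
#' @return A [QsarDataset-class].
#' @export
readQsarDataset <- function(manifest_path) {
  mf <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("ligand_id", "pose_file", "exp_pic50", "split")
  if (!all(need %in% names(mf)))
    .afp_stop(paste("manifest needs columns:", paste(need, collapse = ",")),
              "afp_format_error")
  if (nrow(mf) == 0)
    .afp_stop("empty manifest", "afp_empty_input")
  base <- dirname(manifest_path)
  ensembles <- lapply(seq_len(nrow(mf)), function(i) {
    traj <- readPDB(file.path(base, mf$pose_file[i]),
                    chargeFile = if ("charge_file" %in% names(mf))
                      file.path(base, mf$charge_file[i]) else NULL)
    poses <- lapply(seq_len(nFrames(traj)), function(f)
      perceiveBonds(frameSystem(traj, f)))
    en <- if ("energy_file" %in% names(mf))
      utils::read.csv(file.path(base, mf$energy_file[i]))$conf_energy
    else rep(0, length(poses))
    poseEnsemble(mf$ligand_id[i], poses, en)
  })
  qsarDataset(mf$ligand_id, ensembles, mf$exp_pic50, mf$split)
}
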