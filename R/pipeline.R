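default_config <- function() {
  list(
    pdb = character(0),
    fasta = NULL,
    alignment = NULL,
    scr_intervals = NULL,
    radii = NULL,
    probe = 1.4,
    n_points = 960,
    reference = list(mode = "packaged", n = 30, seed = 20220424),
    thresholds = list(nucleus = 0.2, surface = 0.5),
    scr = list(min_len = 5, min_conservation = 0.5, value = "total"),
    clustering = list(standardize = FALSE),
    denominator = "classified",
    out_dir = ".",
    seed = 1L)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full SASA characterization and clustering pipeline
#'
#' Orchestrates all stages over a set of single-chain structures and their
#' sequences: sequence descriptors and compositions, Chou-Fasman secondary
#' structure, per-residue SASA profiles, nucleus/surface classification
#' against the Gly-X-Gly reference, SCR detection and SASA fingerprints with
#' their correlation matrix, and Ward/Euclidean clustering of both the
#' whole-protein summary vectors and the fingerprints. All outputs are
#' tab-separated tables plus two Newick dendrograms and a provenance JSON;
#' a rerun with the same config is byte-identical.
#'
#' @param config a config list (see `default_config` fields in the source) or
#'   the path of a YAML file holding one. Required fields: `pdb` (named
#'   vector/list of PDB paths), `fasta` (sequences), and `alignment` (aligned
#'   FASTA) or `scr_intervals` (BED-like TSV) for the SCR stage.
#' @return invisibly, a list with every intermediate result and the paths of
#'   the written reports
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  radii <- stage("radii", {
    r <- if (!is.null(cfg$radii)) read_radii(cfg$radii) else radii_table()
    radii_table(r$values, probe = cfg$probe)
  })

  structures <- stage("structure input", {
    if (!length(cfg$pdb)) stop("no PDB inputs configured")
    paths <- unlist(cfg$pdb)
    ids <- names(paths)
    if (is.null(ids) || any(!nzchar(ids)))
      ids <- tools::file_path_sans_ext(basename(paths))
    out <- lapply(paths, read_pdb, radii = radii)
    names(out) <- ids
    for (i in seq_along(out)) out[[i]]$id <- ids[i]
    out
  })

  seqs <- stage("sequence input", {
    if (!is.null(cfg$fasta)) read_fasta(cfg$fasta)
    else vapply(structures, `[[`, character(1), "sequence")
  })

  desc <- stage("descriptors", descriptor_table(seqs))
  comp <- stage("composition", {
    rows <- t(vapply(seqs, composition, integer(20)))
    data.frame(id = names(seqs), Length = nchar(seqs), rows,
               stringsAsFactors = FALSE)
  })
  ss <- stage("secondary structure", ss_table(seqs))

  profiles <- stage("sasa", lapply(structures, sasa_profile,
                                   radii = radii, n_points = cfg$n_points))

  ref <- stage("reference", {
    if (identical(cfg$reference$mode, "packaged")) default_reference()
    else build_reference(cfg$reference$n, cfg$reference$seed, radii,
                         cfg$n_points)
  })

  env <- stage("classification", {
    lapply(names(profiles), function(id) {
      labels <- classify_residues(profiles[[id]], ref,
                                  surface = cfg$thresholds$surface,
                                  nucleus = cfg$thresholds$nucleus)
      list(labels = labels,
           summary = summarize_environment(profiles[[id]], labels,
                                           denominator = cfg$denominator))
    }) -> out
    names(out) <- names(profiles)
    out
  })

  env_tab <- do.call(rbind, lapply(names(env), function(id) {
    s <- env[[id]]$summary
    data.frame(id = id, environment = c("nucleus", "surface"),
               Total = c(s$nucleus_total, s$surface_total),
               Apolar = c(s$nucleus_apolar, s$surface_apolar),
               Backbone = c(s$nucleus_backbone, s$surface_backbone),
               Sidechain = c(s$nucleus_sidechain, s$surface_sidechain),
               Total.Ave.SASA = s$total_ave_sasa, stringsAsFactors = FALSE)
  }))

  scrs <- stage("scr detection", {
    if (!is.null(cfg$alignment)) {
      aln <- read_fasta(cfg$alignment, aligned = TRUE)
      if (!is.null(cfg$scr_intervals))
        read_scr_intervals(cfg$scr_intervals, aln)
      else identify_scrs(aln, min_len = cfg$scr$min_len,
                         min_conservation = cfg$scr$min_conservation)
    } else if (!is.null(cfg$scr_intervals)) {
      stop("scr_intervals require an alignment to map columns onto residues")
    } else {
      stop("supply an 'alignment' (aligned FASTA) or 'scr_intervals' + ",
           "'alignment' to define conserved regions")
    }
  })

  fps <- stage("fingerprints", scr_fingerprint(profiles, scrs,
                                               value = cfg$scr$value))
  corr <- stage("correlation", correlation_matrix(fps))
  prefs <- stage("residue preferences", residue_preferences(scrs, seqs))

  sumvecs <- stage("summary vectors", {
    v <- lapply(names(profiles), function(id)
      summary_vector(profiles[[id]], env[[id]]$summary))
    names(v) <- names(profiles)
    v
  })
  tree_protein <- stage("clustering (whole protein)",
    cluster_observations(sumvecs,
                         standardize = isTRUE(cfg$clustering$standardize)))
  tree_scr <- stage("clustering (SCR fingerprint)",
    cluster_observations(fps,
                         standardize = isTRUE(cfg$clustering$standardize)))

  out <- function(f) file.path(cfg$out_dir, f)
  paths <- c(
    descriptors = write_tsv(desc, out("descriptors.tsv")),
    composition = write_tsv(comp, out("composition.tsv")),
    secondary_structure = write_tsv(ss, out("secondary_structure.tsv")),
    environment = write_tsv(env_tab, out("environment_summary.tsv")),
    fingerprints = write_tsv(
      data.frame(id = names(fps), do.call(rbind, fps)), out("fingerprints.tsv")),
    correlation = write_tsv(
      data.frame(id = rownames(corr), round(corr, 2)), out("correlation.tsv")),
    preferences = write_tsv(
      data.frame(aa = names(prefs), count = as.integer(prefs)),
      out("residue_preferences.tsv")))
  writeLines(to_newick(tree_protein), out("tree_protein.nwk"))
  writeLines(to_newick(tree_scr), out("tree_scr.nwk"))
  paths <- c(paths, tree_protein = out("tree_protein.nwk"),
             tree_scr = out("tree_scr.nwk"))

  provenance <- list(
    package = "scrsasa",
    version = as.character(utils::packageVersion("scrsasa")),
    config = cfg,
    n_proteins = length(structures),
    reference = list(ensemble_size = attr(ref, "ensemble_size"),
                     seed = attr(ref, "seed")))
  jsonlite::write_json(provenance, out("provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, provenance = out("provenance.json"))

  message(sprintf("pipeline: %d proteins, %d SCR columns, reports in %s",
                  length(structures), scrs$n_columns, cfg$out_dir))

  invisible(list(config = cfg, structures = structures, sequences = seqs,
                 descriptors = desc, composition = comp,
                 secondary_structure = ss, profiles = profiles,
                 reference = ref, environment = env, scrs = scrs,
                 fingerprints = fps, correlation = corr,
                 preferences = prefs, summary_vectors = sumvecs,
                 tree_protein = tree_protein, tree_scr = tree_scr,
                 paths = paths))
}

#' Write a synthetic family to disk as pipeline-ready inputs
#'
#' Emits one PDB per member, the sequences as FASTA, the ground-truth
#' alignment as aligned FASTA and the planted group labels as TSV.
#'
#' @param family result of [make_family()]
#' @param dir output directory
#' @return named vector of written paths
#' @export
write_family <- function(family, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- vapply(names(family$structures), function(id) {
    write_pdb(family$structures[[id]], file.path(dir, paste0(id, ".pdb")))
  }, character(1))
  fasta <- write_fasta(family$sequences, file.path(dir, "sequences.fasta"))
  aln <- write_fasta(family$alignment, file.path(dir, "alignment.fasta"))
  labels <- write_tsv(data.frame(id = names(family$labels),
                                 group = as.integer(family$labels)),
                      file.path(dir, "labels.tsv"))
  c(pdb, fasta = fasta, alignment = aln, labels = labels)
}
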