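## Writers (FASTA, search TSV, pepXML, filter reports), the flat key=value
## run configuration, and the end-to-end pipeline entry points used by the
## command-line script.

#' Write a ProteinDb as FASTA
#'
#' @param db a [ProteinDb-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFastaDb <- function(db, path) {
  aa <- db@sequences
  hdr <- names(aa)
  has_desc <- nzchar(db@description)
  names(aa) <- ifelse(has_desc, paste(hdr, db@description), hdr)
  Biostrings::writeXStringSet(aa, path, width = 70L)
  invisible(path)
}

#' Write / read the tab-delimited search report
#'
#' One row per reported PSM: scan, assumed charge, peptide, parent
#' proteins, decoy flag, missed cleavages, calculated and measured
#' precursor mass, the three scores and per-scorer ranks.
#'
#' @param psms search result from [ensembleSearch()].
#' @param path file path.
#' @return `writeSearchTsv` returns `path` invisibly; `readSearchTsv` the
#'   PSM `data.frame`.
#' @export
writeSearchTsv <- function(psms, path) {
  data.table::fwrite(psms, path, sep = "\t")
  invisible(path)
}

#' @rdname writeSearchTsv
#' @export
readSearchTsv <- function(path) {
  need <- c("scan", "charge", "sequence", "proteins", "is_decoy",
            "missed_cleavages", "calc_mass", "meas_mass",
            "mvh", "xcorr", "wdp", "rank_mvh", "rank_xcorr", "rank_wdp")
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("search report is missing column(s): ", paste(missing, collapse = ", "))
  df
}

#' Write search results as pepXML
#'
#' Minimal pepXML dialect for third-party filtering tools: one
#' `spectrum_query` per (scan, assumed charge), one `search_hit` per
#' reported PSM ranked by MVH, with the three scores as named
#' `search_score` entries (`"mvh"`, `"xcorr"`, `"wdp"`).
#'
#' @param psms search result from [ensembleSearch()].
#' @param path output path.
#' @param fasta_path database path recorded in the header.
#' @return `path`, invisibly.
#' @export
writePepXml <- function(psms, path, fasta_path = "database.fasta") {
  doc <- xml2::xml_new_root(
    "msms_pipeline_analysis",
    xmlns = "http://regis-web.systemsbiology.net/pepXML",
    date = "1970-01-01T00:00:00", summary_xml = basename(path))
  run <- xml2::xml_add_child(doc, "msms_run_summary",
                             base_name = tools::file_path_sans_ext(basename(path)),
                             raw_data_type = "raw", raw_data = ".mgf")
  ss <- xml2::xml_add_child(run, "search_summary",
                            base_name = tools::file_path_sans_ext(basename(path)),
                            search_engine = "ensemble", precursor_mass_type = "monoisotopic",
                            fragment_mass_type = "monoisotopic", search_id = "1")
  xml2::xml_add_child(ss, "search_database", local_path = fasta_path,
                      type = "AA")
  if (nrow(psms)) {
    key <- paste(psms$scan, psms$charge)
    idx <- 0L
    for (grp in split(seq_len(nrow(psms)), key)) {
      rows <- psms[grp, ]
      rows <- rows[order(rows$rank_mvh), ]
      idx <- idx + 1L
      q <- xml2::xml_add_child(run, "spectrum_query",
        spectrum = rows$scan[1L],
        start_scan = as.character(idx), end_scan = as.character(idx),
        precursor_neutral_mass = sprintf("%.6f", rows$meas_mass[1L]),
        assumed_charge = as.character(rows$charge[1L]), index = as.character(idx))
      sr <- xml2::xml_add_child(q, "search_result")
      for (i in seq_len(nrow(rows))) {
        prot <- strsplit(rows$proteins[i], ";", fixed = TRUE)[[1]]
        h <- xml2::xml_add_child(sr, "search_hit",
          hit_rank = as.character(rows$rank_mvh[i]),
          peptide = rows$sequence[i],
          protein = prot[1L],
          num_tot_proteins = as.character(length(prot)),
          calc_neutral_pep_mass = sprintf("%.6f", rows$calc_mass[i]),
          massdiff = sprintf("%.6f", rows$meas_mass[i] - rows$calc_mass[i]),
          num_missed_cleavages = as.character(rows$missed_cleavages[i]),
          is_rejected = "0")
        for (p in prot[-1L])
          xml2::xml_add_child(h, "alternative_protein", protein = p)
        xml2::xml_add_child(h, "search_score", name = "mvh",
                            value = sprintf("%.6f", rows$mvh[i]))
        xml2::xml_add_child(h, "search_score", name = "xcorr",
                            value = sprintf("%.6f", rows$xcorr[i]))
        xml2::xml_add_child(h, "search_score", name = "wdp",
                            value = sprintf("%.6f", rows$wdp[i]))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read the three ensemble scores back from a pepXML file
#'
#' @param path pepXML path written by [writePepXml()].
#' @return `data.frame` with `scan`, `charge`, `sequence`, `mvh`, `xcorr`,
#'   `wdp`.
#' @export
readPepXmlScores <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  qs <- xml2::xml_find_all(doc, ".//spectrum_query")
  rows <- lapply(qs, function(q) {
    hits <- xml2::xml_find_all(q, ".//search_hit")
    if (!length(hits)) return(NULL)
    score_of <- function(h, nm)
      as.numeric(xml2::xml_attr(
        xml2::xml_find_first(h, sprintf(".//search_score[@name='%s']", nm)),
        "value"))
    data.frame(
      scan = xml2::xml_attr(q, "spectrum"),
      charge = as.integer(xml2::xml_attr(q, "assumed_charge")),
      sequence = xml2::xml_attr(hits, "peptide"),
      mvh = vapply(hits, score_of, 0.0, nm = "mvh"),
      xcorr = vapply(hits, score_of, 0.0, nm = "xcorr"),
      wdp = vapply(hits, score_of, 0.0, nm = "wdp"))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(scan = character(), charge = integer(),
                      sequence = character(), mvh = numeric(),
                      xcorr = numeric(), wdp = numeric())
  out
}

#' Read / write a flat key=value run configuration
#'
#' The configuration file holds one `key = value` pair per line (`#`
#' comments allowed). Keys must be known [runConfig()] entries; unknown
#' keys are rejected. Vector values are comma-separated.
#'
#' @param path file path.
#' @param config a [runConfig()] list.
#' @return `readRunConfig` returns a [runConfig()] list; `writeRunConfig`
#'   returns `path` invisibly.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), "")
  defaults <- runConfig()
  bad <- setdiff(keys, names(defaults))
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg <- defaults
  for (i in seq_along(keys)) {
    proto <- defaults[[keys[i]]]
    v <- strsplit(vals[i], ",")[[1]]
    cfg[[keys[i]]] <- if (is.numeric(proto)) {
      out <- as.numeric(v)
      if (is.integer(proto)) as.integer(out) else out
    } else if (is.logical(proto)) as.logical(v) else v
  }
  cfg
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", paste(config[[k]], collapse = ",")), "")
  writeLines(lines, path)
  invisible(path)
}

#' Full run configuration with defaults
#'
#' Union of the search tunables ([searchConfig()]) and the filtering /
#' assembly tunables: target FDR level (default 0.01), filtering level
#' (`psm`), classifier (`logistic_regression`), decoy test-split fraction
#' `alpha` (0.5) and split seed.
#'
#' @param ... name = value overrides; unknown names are an error.
#' @return Named list.
#' @export
runConfig <- function(...) {
  cfg <- c(searchConfig(), list(
    target_fdr = 0.01,
    fdr_level = "psm",
    model_kind = "logistic_regression",
    alpha = 0.5,
    split_seed = 20170922L,
    l2_strength = 1.0,
    min_unique_peptides = 1L
  ))
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  modifyList(cfg, ov)
}

.searchCfgOf <- function(cfg) do.call(searchConfig, cfg[names(searchConfig())])

#' Run the ensemble search pipeline
#'
#' Reads the FASTA database, appends reversed decoys, digests and indexes,
#' reads the MGF, runs the two-tier three-scorer search, and writes the
#' tab-delimited and pepXML reports plus the resolved configuration.
#'
#' @param fasta,mgf input paths.
#' @param out_dir output directory.
#' @param config a [runConfig()] list.
#' @return List with `psms`, `index`, `db`, and output `paths`.
#' @export
runSearch <- function(fasta, mgf, out_dir, config = runConfig()) {
  if (!file.exists(fasta)) stop("FASTA not found: ", fasta)
  if (!file.exists(mgf)) stop("MGF not found: ", mgf)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  db <- readFasta(fasta, decoy_prefix = cfg$decoy_prefix)
  if (!any(db@isDecoy)) db <- generateDecoys(db, cfg$decoy_prefix)
  index <- buildMassIndex(db, cfg$max_missed, cfg$length_range, cfg$fixed_mods)
  spectra <- readMgf(mgf, assumed_charges = cfg$assumed_charges)
  message(sprintf("search: %d spectra against %d peptides", length(spectra),
                  nrow(peptideTable(index))))
  psms <- ensembleSearch(spectra, index, .searchCfgOf(cfg))
  paths <- list(
    tsv = file.path(out_dir, "search_psms.tsv"),
    pepxml = file.path(out_dir, "search_psms.pep.xml"),
    config = file.path(out_dir, "search_config.txt"))
  writeSearchTsv(psms, paths$tsv)
  writePepXml(psms, paths$pepxml, fasta_path = fasta)
  writeRunConfig(cfg, paths$config)
  list(psms = psms, index = index, db = db, paths = paths)
}

#' Run the ensemble filtering and assembly pipeline
#'
#' Splits the decoy proteins, extracts the 10 PSM features with agreement
#' classes, trains the supervised filter on unanimous target PSMs vs
#' training-split decoy PSMs, selects one PSM per spectrum, thresholds at
#' the configured FDR, assembles peptides and protein groups, and writes
#' the filter / peptide / protein reports.
#'
#' @param psms search result (`data.frame` or path to a search TSV).
#' @param db target+decoy [ProteinDb-class] used for the search.
#' @param index the [MassIndex-class] used for the search.
#' @param out_dir output directory (`NULL` to skip writing).
#' @param config a [runConfig()] list.
#' @return List with the split `db`, feature table `features`, trained
#'   `filter`, per-spectrum `selected` table, `psm_filter` (threshold,
#'   accepted set and FDR record from [filterAtFdr()]), `peptides`,
#'   `protein_groups`, and `fdr` records at the three levels.
#' @export
runFilter <- function(psms, db, index, out_dir = NULL, config = runConfig()) {
  cfg <- config
  if (is.character(psms)) psms <- readSearchTsv(psms)
  db <- splitDecoyProteins(db, alpha = cfg$alpha, seed = cfg$split_seed)
  alpha <- realizedAlpha(db)
  message(sprintf("filter: decoy split seed %d, realized alpha %.4f",
                  cfg$split_seed, alpha))
  feat <- extractFeatures(psms)
  feat <- annotateDecoySplit(feat, db)
  message(sprintf("filter: %d rank-1 PSMs (%s)", nrow(feat),
                  paste(names(table(feat$class)), table(feat$class),
                        sep = "=", collapse = ", ")))
  train <- buildTrainingData(feat, db)
  filter <- trainPsmFilter(train$positives, train$negatives,
                           model_kind = cfg$model_kind, alpha = alpha,
                           l2_strength = cfg$l2_strength)
  selected <- selectPsmPerSpectrum(feat, filter)
  res <- filterAtFdr(selected, alpha, target_fdr = cfg$target_fdr,
                     level = cfg$fdr_level, index = index, db = db,
                     decoy_prefix = cfg$decoy_prefix)
  accepted <- res$accepted
  peptides <- assemblePeptides(accepted)
  groups <- inferProteins(peptides, index, min_unique = cfg$min_unique_peptides,
                          decoy_prefix = cfg$decoy_prefix)
  fdr <- list(
    psm = res$fdr,
    peptide = levelFdrCounts(peptides, db, alpha),
    protein = levelFdrCounts(groups, db, alpha))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    selected_out <- selected
    selected_out$accepted <- selected_out$scan %in% accepted$scan &
      selected_out$sequence %in% accepted$sequence
    data.table::fwrite(selected_out, file.path(out_dir, "filter_psms.tsv"), sep = "\t")
    data.table::fwrite(peptides, file.path(out_dir, "peptides.tsv"), sep = "\t")
    data.table::fwrite(groups, file.path(out_dir, "protein_groups.tsv"), sep = "\t")
    summary_lines <- c(
      sprintf("threshold = %s", format(res$threshold)),
      sprintf("alpha = %.6f", alpha),
      sprintf("split_seed = %d", cfg$split_seed),
      sprintf("psm: target=%d test_decoy=%d fdr=%.6f", fdr$psm$n_target,
              fdr$psm$n_test_decoy, fdr$psm$fdr),
      sprintf("peptide: target=%d test_decoy=%d fdr=%.6f", fdr$peptide$n_target,
              fdr$peptide$n_test_decoy, fdr$peptide$fdr),
      sprintf("protein: target=%d test_decoy=%d fdr=%.6f", fdr$protein$n_target,
              fdr$protein$n_test_decoy, fdr$protein$fdr))
    writeLines(summary_lines, file.path(out_dir, "filter_summary.txt"))
    writeRunConfig(cfg, file.path(out_dir, "filter_config.txt"))
  }
  list(db = db, features = feat, filter = filter, selected = selected,
       psm_filter = res, accepted = accepted, peptides = peptides,
       protein_groups = groups, fdr = fdr)
}
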