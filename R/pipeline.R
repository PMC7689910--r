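# End-to-end orchestration: run the independent analysis stages from a
# single config and join them into a per-residue summary table.

#' Run the full per-residue analysis pipeline
#'
#' Executes the configured stages in dependency order and joins their
#' results into one row per residue. Stages are independently optional;
#' columns of skipped stages are NA (never silently defaulted). Residue
#' numbering across inputs is reconciled only through explicit per-input
#' `offset` declarations; a residue-type clash between an input and the
#' declared sequence is a hard error listing the mismatches.
#'
#' @param config A named list or the path of a YAML file. Recognised blocks:
#' \describe{
#'   \item{sequence}{`fasta` (path) or `residues` (string), optional
#'     `offset`.}
#'   \item{csp}{`free`, `bound` (shift-table TSVs) or in-memory
#'     `shift_table`s; `alpha` (default 0.14), `threshold` (default 0.15
#'     ppm).}
#'   \item{ssp}{`free` and/or `bound` shift tables; `window` (default 5).}
#'   \item{tempco}{`series`: peak-list paths; `temperatures` (K).}
#'   \item{relaxation}{`t1`, `t2` (decay TSVs), `noe_sat`, `noe_unsat`
#'     (TSVs `residue intensity`), `freq_1H` (MHz, default 700.17).}
#'   \item{ensemble}{`pdb` (multi-MODEL path) or an `ensemble` object;
#'     `chain`, `partner_chain`, `offset`, `contact_cutoff` (default 4.5
#'     A), `cluster_cutoff` (default 1.0 A).}
#' }
#' @param out_dir Optional output directory; writes `summary.tsv`,
#'   per-stage TSV reports and a YAML run manifest with parameters and
#'   input checksums.
#' @return data.frame of class `residue_summary` (one row per residue) with
#'   the per-stage results as attribute `"stages"`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  log_msg <- function(...) message("[fuzzynmr] ", sprintf(...))
  stages <- list()
  inputs <- character()

  seq <- NULL
  if (!is.null(config$sequence)) {
    sc <- config$sequence
    off <- sc$offset %||% 0L
    seq <- if (!is.null(sc$fasta)) {
      inputs <- c(inputs, sc$fasta)
      read_fasta_sequence(sc$fasta, offset = off)
    } else protein_sequence(sc$residues, id = sc$id %||% "seq", offset = off)
    log_msg("sequence '%s': %d residues", seq$id, length(seq$residues))
  }

  check_numbering <- function(tab, what) {
    if (is.null(seq)) return(invisible())
    rt <- residue_type_at(seq, tab$residue_index)
    bad <- which(!is.na(rt) & !is.na(tab$residue_type) &
                   rt != tab$residue_type)
    out_of_range <- unique(tab$residue_index[is.na(rt)])
    if (length(bad) || length(out_of_range)) {
      msgs <- c(
        if (length(out_of_range))
          paste0("outside sequence: ",
                 paste(out_of_range, collapse = ", ")),
        if (length(bad))
          paste0("type mismatch at ",
                 paste0(unique(tab$residue_index[bad]), collapse = ", ")))
      stop("residue numbering inconsistent for ", what,
           " (declare an offset?): ", paste(msgs, collapse = "; "))
    }
  }

  load_shift <- function(x, state) {
    if (inherits(x, "shift_table")) return(x)
    inputs <<- c(inputs, x)
    read_shift_table(x, state = state)
  }

  if (!is.null(config$csp)) {
    cc <- config$csp
    free <- load_shift(cc$free, "free")
    bound <- load_shift(cc$bound, "bound")
    check_numbering(free, "csp free shifts")
    check_numbering(bound, "csp bound shifts")
    prof <- classify_perturbed(
      cumulative_delta(free, bound, alpha = cc$alpha %||% 0.14),
      threshold = cc$threshold %||% 0.15)
    stages$csp <- prof
    stages$csp_regions <- contiguous_regions(prof, min_len = cc$min_len %||% 3L)
    log_msg("csp: %d residues, %d perturbed, %d broadened",
            nrow(prof), sum(prof$perturbed), sum(prof$broadened))
  }

  if (!is.null(config$ssp)) {
    sc <- config$ssp
    if (is.null(seq)) stop("ssp stage requires a sequence block")
    for (state in c("free", "bound")) {
      if (is.null(sc[[state]])) next
      tab <- load_shift(sc[[state]], state)
      check_numbering(tab, paste("ssp", state, "shifts"))
      sec <- secondary_shifts(tab, seq)
      stages[[paste0("ssp_", state)]] <-
        ssp_profile(sec, window = sc$window %||% 5L)
      log_msg("ssp (%s): %d residues", state,
              nrow(stages[[paste0("ssp_", state)]]))
    }
  }

  if (!is.null(config$tempco)) {
    tc <- config$tempco
    series <- lapply(seq_along(tc$series), function(i) {
      inputs <<- c(inputs, tc$series[[i]])
      read_peaklist_sparky(tc$series[[i]],
                           temperature = tc$temperatures[[i]])
    })
    stages$tempco <- temp_coefficients(series)
    log_msg("tempco: %d residues fitted", nrow(stages$tempco))
  }

  if (!is.null(config$relaxation)) {
    rc <- config$relaxation
    ctx <- spectrometer_context(rc$freq_1H %||% 700.17)
    t1 <- if (inherits(rc$t1, "decay_series")) rc$t1
          else { inputs <- c(inputs, rc$t1); read_decay_series(rc$t1, "T1") }
    t2 <- if (inherits(rc$t2, "decay_series")) rc$t2
          else { inputs <- c(inputs, rc$t2); read_decay_series(rc$t2, "T2") }
    load_int <- function(x) {
      if (is.data.frame(x)) return(x)
      inputs <<- c(inputs, x)
      utils::read.table(x, header = FALSE, comment.char = "#",
                        col.names = c("residue_index", "intensity"))
    }
    noe <- het_noe(load_int(rc$noe_sat), load_int(rc$noe_unsat),
                   noise = rc$noise %||% 0)
    rec <- relaxation_record(fit_exponential_decay(t1),
                             fit_exponential_decay(t2), noe, ctx)
    stages$relaxation <- rec
    stages$jmap <- group_residues(reduced_spectral_density(rec),
                                  exchange_factor = rc$exchange_factor %||% 2)
    log_msg("relaxation: %d residues with R1/R2/NOE", nrow(rec))
  }

  if (!is.null(config$ensemble)) {
    ec <- config$ensemble
    ens <- if (inherits(ec$pdb, "ensemble")) ec$pdb
           else { inputs <- c(inputs, ec$pdb); read_ensemble_pdb(ec$pdb) }
    chain <- ec$chain %||% ens$atoms$chain[1]
    eoff <- ec$offset %||% 0L
    if (eoff != 0L) ens$atoms$residue_index <- ens$atoms$residue_index + eoff
    etab <- unique(ens$atoms[ens$atoms$chain == chain,
                             c("residue_index", "residue_type")])
    check_numbering(etab, "ensemble")
    sel <- select_atoms(ens, chain = chain,
                        atom_names = c("N", "CA", "C", "O"))
    aligned <- superpose(ens, sel)
    stages$bfactors <- bfactors(aligned)
    stages$bfactors <- stages$bfactors[stages$bfactors$chain == chain, ]
    stages$helix <- helix_fraction(ens, chain = chain)
    stages$clusters <- gromos_cluster(ens, sel,
                                      cutoff = ec$cluster_cutoff %||% 1.0)
    if (!is.null(ec$partner_chain)) {
      stages$contacts <- residue_contacts(ens, chain, ec$partner_chain,
                                          cutoff = ec$contact_cutoff %||% 4.5)
    }
    log_msg("ensemble: %d snapshots, %d clusters", n_snapshots(ens),
            length(stages$clusters$sizes))
  }

  ## join everything residue-wise
  all_idx <- sort(unique(c(
    if (!is.null(seq)) residue_indices(seq),
    stages$csp$residue_index, stages$ssp_free$residue_index,
    stages$ssp_bound$residue_index, stages$tempco$residue_index,
    stages$relaxation$residue_index, stages$bfactors$residue_index)))
  pull <- function(df, col, idx_col = "residue_index") {
    if (is.null(df)) return(rep(NA, length(all_idx)))
    df[[col]][match(all_idx, df[[idx_col]])]
  }
  summary <- data.frame(
    residue_index = all_idx,
    residue_type = if (!is.null(seq)) residue_type_at(seq, all_idx)
                   else pull(stages$csp, "residue_type"),
    delta_cum = pull(stages$csp, "delta_cum"),
    perturbed = pull(stages$csp, "perturbed"),
    broadened = pull(stages$csp, "broadened"),
    ssp_free = pull(stages$ssp_free, "ssp"),
    ssp_bound = pull(stages$ssp_bound, "ssp"),
    tempco_class = pull(stages$tempco, "class"),
    R1 = pull(stages$relaxation, "R1"),
    R2 = pull(stages$relaxation, "R2"),
    hetNOE = pull(stages$relaxation, "noe"),
    J0 = pull(stages$jmap, "J0"),
    JwN = pull(stages$jmap, "JwN"),
    mobility_group = as.character(pull(stages$jmap, "group")),
    helix_fraction = pull(stages$helix, "helix_fraction"),
    B = pull(stages$bfactors, "B"),
    stringsAsFactors = FALSE)
  summary$anchor_flag <- if (!is.null(stages$contacts)) {
    vapply(all_idx, function(r)
      any(stages$contacts$residue_a == r &
            stages$contacts$frequency >= 0.5), NA)
  } else NA
  attr(summary, "stages") <- stages
  class(summary) <- c("residue_summary", "data.frame")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(stages)) {
      if (is.data.frame(stages[[nm]]))
        utils::write.table(as.data.frame(stages[[nm]]),
                           file.path(out_dir, paste0(nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    sanitize <- function(x) {
      if (is.object(x) || is.function(x)) return(paste0("<", class(x)[1], ">"))
      if (is.list(x)) return(lapply(x, sanitize))
      x
    }
    manifest <- list(
      parameters = sanitize(config),
      inputs = lapply(unique(inputs[file.exists(inputs)]), function(p)
        list(path = p, md5 = unname(tools::md5sum(p)))),
      n_residues = nrow(summary))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  summary
}
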