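# Data model and readers/writers shared by all analysis stages.

#' Protein sequence with numbering offset
#'
#' @param residues Character: either a single string of 1-letter codes or a
#'   character vector of single codes.
#' @param id Label for the sequence.
#' @param offset Integer added to the 1-based position to obtain the residue
#'   index used in all tables (offset 0: first residue is residue 1; offset 1
#'   numbers a construct starting at residue 2, etc.).
#' @return Object of class `protein_sequence`.
#' @examples
#' p53 <- protein_sequence(p53tad_sequence(), id = "p53TAD1-60")
#' @export
protein_sequence <- function(residues, id = "seq", offset = 0L) {
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(residues)
  bad <- setdiff(unique(residues), AMINO_ACIDS)
  if (length(bad))
    stop("non-canonical residue code(s): ", paste(bad, collapse = ", "))
  if (!length(residues)) stop("empty sequence")
  out <- list(id = id, residues = residues, offset = as.integer(offset))
  class(out) <- "protein_sequence"
  out
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("protein_sequence '%s': %d residues (%d-%d)\n", x$id,
              length(x$residues), x$offset + 1L, x$offset + length(x$residues)))
  invisible(x)
}

#' Residue indices covered by a sequence
#' @param seq A `protein_sequence`.
#' @return Integer vector of residue indices.
#' @export
residue_indices <- function(seq) {
  seq$offset + seq_along(seq$residues)
}

#' Residue type at given residue indices
#' @param seq A `protein_sequence`.
#' @param index Residue indices (numbering includes the offset).
#' @return Character vector of 1-letter codes (NA outside the sequence).
#' @export
residue_type_at <- function(seq, index) {
  pos <- index - seq$offset
  out <- rep(NA_character_, length(index))
  ok <- pos >= 1L & pos <= length(seq$residues)
  out[ok] <- seq$residues[pos[ok]]
  out
}

#' The p53TAD 1-60 sequence (UniProt P04637, residues 1-60)
#' @return Single string of 1-letter codes, M1...P60.
#' @export
p53tad_sequence <- function() P53TAD_SEQ

#' Read a protein sequence from FASTA
#' @param path FASTA file; the first record is used.
#' @param offset Numbering offset (see [protein_sequence()]).
#' @return A `protein_sequence`.
#' @export
read_fasta_sequence <- function(path, offset = 0L) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE)
  if (!length(recs)) stop("no sequences in ", path)
  protein_sequence(toupper(as.character(recs[[1]])),
                   id = attr(recs[[1]], "name"), offset = offset)
}

#' Average molecular mass of a protein chain
#'
#' Sum of average residue masses plus one water (18.02 Da). For p53TAD 1-60
#' this evaluates to ~6.8 kDa, i.e. the 7 kDa species that binds the ~24 kDa
#' S100A4 dimer to give the 31 kDa complex.
#'
#' @param seq A `protein_sequence` or a string of 1-letter codes.
#' @return Mass in Da.
#' @examples
#' average_mass("G")   # 75.07
#' average_mass(p53tad_sequence()) / 1000  # ~6.8 kDa
#' @export
average_mass <- function(seq) {
  if (is.character(seq)) seq <- protein_sequence(seq)
  sum(AVERAGE_RESIDUE_MASS[seq$residues]) + WATER_MASS
}

# ---------------------------------------------------------------------------
# shift tables

#' Construct a per-residue chemical shift table
#'
#' @param residue_index 1-based residue indices.
#' @param residue_type 1-letter codes.
#' @param nucleus Nucleus codes among H, N, HA, CA, CB, C.
#' @param shift Chemical shifts (ppm).
#' @param protein_id,state Labels; `state` is typically "free" or "bound".
#' @return A data.frame of class `shift_table` with one row per
#'   (residue, nucleus).
#' @export
shift_table <- function(residue_index, residue_type, nucleus, shift,
                        protein_id = "protein", state = "free") {
  df <- data.frame(residue_index = as.integer(residue_index),
                   residue_type = as.character(residue_type),
                   nucleus = as.character(nucleus),
                   shift = as.numeric(shift),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$nucleus), VALID_NUCLEI)
  if (length(bad)) stop("unknown nucleus code(s): ", paste(bad, collapse = ", "))
  key <- paste(df$residue_index, df$nucleus, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate shift entry for ", key[duplicated(key)][1])
  pro_amide <- df$residue_type == "P" & df$nucleus %in% c("H", "N")
  if (any(pro_amide))
    stop("proline residue(s) cannot carry amide H/N shifts: residue ",
         paste(unique(df$residue_index[pro_amide]), collapse = ", "))
  df <- df[order(df$nucleus, df$residue_index), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "protein_id") <- protein_id
  attr(df, "state") <- state
  class(df) <- c("shift_table", "data.frame")
  df
}

#' Read a chemical shift table
#'
#' Supported dialects: `"tsv"` (whitespace-separated columns
#' `residue_index residue_type nucleus shift_ppm`, `#` comments) and
#' `"nmrstar-minimal"` (the assigned-chemical-shift loop of an NMR-STAR file;
#' only `Seq_ID`, `Comp_ID`, `Atom_ID`, `Val` are consumed).
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"nmrstar-minimal"`.
#' @param protein_id,state Labels attached to the result.
#' @return A `shift_table`.
#' @export
read_shift_table <- function(path, dialect = c("tsv", "nmrstar-minimal"),
                             protein_id = "protein", state = "free") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "tsv") {
    keep <- !grepl("^\\s*(#|$)", lines)
    rows <- strsplit(trimws(lines[keep]), "\\s+")
    lineno <- which(keep)
    ok <- vapply(rows, length, 0L) >= 4L
    bad <- lineno[!ok]
    if (length(bad))
      stop("unparseable row(s) at line(s): ", paste(bad, collapse = ", "))
    shift <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 4L)))
    ridx <- suppressWarnings(as.integer(vapply(rows, `[`, "", 1L)))
    nn <- which(is.na(shift) | is.na(ridx))
    if (length(nn))
      stop("non-numeric field at line(s): ", paste(lineno[nn], collapse = ", "))
    shift_table(ridx, vapply(rows, `[`, "", 2L),
                toupper(vapply(rows, `[`, "", 3L)), shift,
                protein_id = protein_id, state = state)
  } else {
    read_shift_table_star(lines, protein_id = protein_id, state = state)
  }
}

# minimal NMR-STAR: locate the Atom_chem_shift loop and pull the four columns
read_shift_table_star <- function(lines, protein_id, state) {
  tagpat <- "^\\s*_Atom_chem_shift\\.(\\S+)"
  tag_idx <- grep(tagpat, lines)
  if (!length(tag_idx)) stop("no _Atom_chem_shift loop found")
  tags <- sub(tagpat, "\\1", lines[tag_idx])
  need <- c("Seq_ID", "Comp_ID", "Atom_ID", "Val")
  if (!all(need %in% tags))
    stop("shift loop lacks required tag(s): ",
         paste(setdiff(need, tags), collapse = ", "))
  body <- lines[(max(tag_idx) + 1L):length(lines)]
  stop_at <- grep("^\\s*(stop_|loop_|save_)", body)
  if (length(stop_at)) body <- body[seq_len(stop_at[1] - 1L)]
  body <- body[!grepl("^\\s*(#|$)", body)]
  rows <- strsplit(trimws(body), "\\s+")
  ok <- vapply(rows, length, 0L) >= length(tags)
  rows <- rows[ok]
  get <- function(tag) vapply(rows, `[`, "", which(tags == tag)[1])
  comp <- toupper(get("Comp_ID"))
  rtype <- unname(AA_THREE_TO_ONE[comp])
  rtype[is.na(rtype) & comp %in% AMINO_ACIDS] <- comp[is.na(rtype) &
                                                        comp %in% AMINO_ACIDS]
  if (anyNA(rtype)) stop("unknown residue name: ", comp[is.na(rtype)][1])
  shift_table(as.integer(get("Seq_ID")), rtype, toupper(get("Atom_ID")),
              as.numeric(get("Val")), protein_id = protein_id, state = state)
}

#' Write a shift table as TSV
#' @param x A `shift_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# shift table: %s (%s)", attr(x, "protein_id"),
                     attr(x, "state")), con)
  writeLines("# residue_index residue_type nucleus shift_ppm", con)
  writeLines(sprintf("%d\t%s\t%s\t%.6g", x$residue_index, x$residue_type,
                     x$nucleus, x$shift), con)
  invisible(path)
}

#' Extract shifts of one nucleus as a named vector
#' @param x A `shift_table`.
#' @param nucleus Nucleus code.
#' @return Numeric vector named by residue index.
#' @export
shifts_of <- function(x, nucleus) {
  sel <- x$nucleus == nucleus
  stats::setNames(x$shift[sel], x$residue_index[sel])
}

# ---------------------------------------------------------------------------
# peak lists

#' Construct a 2D 15N-1H peak list
#'
#' @param assignment Assignment labels (e.g. "L26N-H") or "?-?" for
#'   unassigned peaks.
#' @param w1 15N coordinates (ppm).
#' @param w2 1H coordinates (ppm).
#' @param height Peak heights (arbitrary units; NA if absent).
#' @param spectrum_id Label.
#' @param titration_fraction Molar ratio of the titration point (0-1.15), or
#'   NA.
#' @param temperature Sample temperature (K), or NA.
#' @return A data.frame of class `peak_list` with parsed `residue_index` /
#'   `residue_type` where assigned.
#' @export
peak_list <- function(assignment, w1, w2, height = NA_real_,
                      spectrum_id = "spectrum", titration_fraction = NA_real_,
                      temperature = NA_real_) {
  if (any(!is.finite(w1)) || any(!is.finite(w2)))
    stop("peak coordinates must be finite")
  parsed <- parse_assignment(assignment)
  df <- data.frame(assignment = assignment,
                   residue_index = parsed$residue_index,
                   residue_type = parsed$residue_type,
                   w1 = as.numeric(w1), w2 = as.numeric(w2),
                   height = rep_len(as.numeric(height), length(w1)),
                   stringsAsFactors = FALSE)
  attr(df, "spectrum_id") <- spectrum_id
  attr(df, "titration_fraction") <- titration_fraction
  attr(df, "temperature") <- temperature
  class(df) <- c("peak_list", "data.frame")
  df
}

parse_assignment <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z])(\\d+)[A-Za-z0-9']*-", label))
  idx <- vapply(m, function(g) if (length(g)) as.integer(g[3]) else NA_integer_,
                0L)
  typ <- vapply(m, function(g) if (length(g)) toupper(g[2]) else NA_character_,
                "")
  typ[is.na(idx)] <- NA_character_
  list(residue_index = idx, residue_type = typ)
}

#' Read a Sparky-style peak list
#'
#' Whitespace-delimited columns: assignment, w1 (15N, ppm), w2 (1H, ppm) and
#' an optional height. A header line starting with "Assignment" is skipped;
#' `?-?` marks unassigned peaks and is preserved.
#'
#' @param path Input file.
#' @param spectrum_id,titration_fraction,temperature Metadata (see
#'   [peak_list()]).
#' @return A `peak_list`.
#' @export
read_peaklist_sparky <- function(path, spectrum_id = basename(path),
                                 titration_fraction = NA_real_,
                                 temperature = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*($|#|Assignment)", lines, ignore.case = TRUE)
  lines_kept <- lines[keep]
  if (!length(lines_kept)) {
    warning("empty peak list: ", path)
    return(peak_list(character(), numeric(), numeric(),
                     spectrum_id = spectrum_id,
                     titration_fraction = titration_fraction,
                     temperature = temperature))
  }
  rows <- strsplit(trimws(lines_kept), "\\s+")
  lineno <- which(keep)
  nf <- vapply(rows, length, 0L)
  if (any(nf < 3L))
    stop("too few columns at line ", lineno[nf < 3L][1])
  w1 <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 2L)))
  w2 <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 3L)))
  bad <- which(is.na(w1) | is.na(w2))
  if (length(bad))
    stop("non-numeric peak coordinate at line ", lineno[bad][1])
  height <- suppressWarnings(as.numeric(vapply(rows, function(r)
    if (length(r) >= 4L) r[4] else NA_character_, "")))
  peak_list(vapply(rows, `[`, "", 1L), w1, w2, height,
            spectrum_id = spectrum_id,
            titration_fraction = titration_fraction,
            temperature = temperature)
}

#' Write a peak list in the Sparky dialect
#' @param x A `peak_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist_sparky <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%-12s %9s %9s %12s", "Assignment", "w1", "w2",
                     "Data Height"), con)
  h <- ifelse(is.na(x$height), "", sprintf("%.6g", x$height))
  writeLines(sprintf("%-12s %9.4f %9.4f %12s", x$assignment, x$w1, x$w2, h),
             con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# conformational ensembles (multi-MODEL PDB)

#' Construct a conformational ensemble
#'
#' @param coords Numeric array `n_atoms x 3 x n_snapshots` (Angstrom).
#' @param atoms data.frame with columns `chain`, `residue_index`,
#'   `residue_type` (1-letter), `atom_name`, `element`.
#' @param id Label.
#' @return Object of class `ensemble`.
#' @export
ensemble <- function(coords, atoms, id = "ensemble") {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L,
            nrow(atoms) == dim(coords)[1])
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  out <- list(coords = coords, atoms = atoms, id = id)
  class(out) <- "ensemble"
  out
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble '%s': %d snapshots, %d atoms, chains %s\n", x$id,
              n_snapshots(x), nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = "/")))
  invisible(x)
}

#' Number of snapshots in an ensemble
#' @param ens An `ensemble`.
#' @return Integer.
#' @export
n_snapshots <- function(ens) dim(ens$coords)[3]

#' Read a multi-MODEL PDB file as an ensemble
#'
#' Snapshots are ordered by MODEL number; a file without MODEL records yields
#' a single-snapshot ensemble. The atom roster (chain, residue, atom name)
#' must be identical across models.
#'
#' @param path PDB file.
#' @return An `ensemble`.
#' @export
read_ensemble_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  atom_sel <- rec %in% c("ATOM  ", "HETATM")
  if (!any(atom_sel)) stop("no ATOM records in ", path)
  model_of <- findInterval(seq_along(lines), model_starts)
  if (!length(model_starts)) model_of <- rep(1L, length(lines))
  model_of[model_of == 0L] <- 1L
  atom_lines <- lines[atom_sel]
  atom_model <- model_of[atom_sel]
  parse_block <- function(ln) {
    data.frame(
      atom_name = trimws(substr(ln, 13, 16)),
      residue_name = trimws(substr(ln, 18, 20)),
      chain = substr(ln, 22, 22),
      residue_index = as.integer(substr(ln, 23, 26)),
      x = as.numeric(substr(ln, 31, 38)),
      y = as.numeric(substr(ln, 39, 46)),
      z = as.numeric(substr(ln, 47, 54)),
      element = trimws(substr(ln, 77, 78)),
      stringsAsFactors = FALSE)
  }
  models <- unique(atom_model)
  blocks <- lapply(models, function(m) parse_block(atom_lines[atom_model == m]))
  ref <- blocks[[1]]
  roster <- function(b) paste(b$chain, b$residue_index, b$atom_name)
  ref_roster <- roster(ref)
  for (i in seq_along(blocks)[-1]) {
    r <- roster(blocks[[i]])
    if (length(r) != length(ref_roster) ||
        any(r != ref_roster[seq_along(r)])) {
      miss <- c(setdiff(ref_roster, r), setdiff(r, ref_roster))
      if (!length(miss)) {
        k <- min(length(r), length(ref_roster))
        miss <- ref_roster[which(r[seq_len(k)] != ref_roster[seq_len(k)])[1]]
      }
      stop("atom roster mismatch in MODEL ", models[i], ": ", miss[1])
    }
  }
  coords <- array(NA_real_, c(nrow(ref), 3L, length(blocks)))
  for (i in seq_along(blocks))
    coords[, , i] <- as.matrix(blocks[[i]][, c("x", "y", "z")])
  rtype <- unname(AA_THREE_TO_ONE[ref$residue_name])
  rtype[is.na(rtype)] <- "X"
  el <- ref$element
  el[el == ""] <- substr(gsub("[0-9]", "", ref$atom_name[el == ""]), 1, 1)
  atoms <- data.frame(chain = ref$chain, residue_index = ref$residue_index,
                      residue_type = rtype, atom_name = ref$atom_name,
                      element = el, stringsAsFactors = FALSE)
  ensemble(coords, atoms, id = basename(path))
}

#' Write an ensemble (or selected snapshots) as a multi-MODEL PDB
#' @param ens An `ensemble`.
#' @param path Output path.
#' @param snapshots Snapshot indices to write (default all).
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path, snapshots = seq_len(n_snapshots(ens))) {
  con <- file(path, "w")
  on.exit(close(con))
  a <- ens$atoms
  res3 <- unname(AA_ONE_TO_THREE[a$residue_type])
  res3[is.na(res3)] <- "UNK"
  for (m in seq_along(snapshots)) {
    writeLines(sprintf("MODEL %8d", m), con)
    xyz <- ens$coords[, , snapshots[m], drop = FALSE]
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)),
      ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name), a$atom_name),
      res3, a$chain, a$residue_index,
      xyz[, 1, 1], xyz[, 2, 1], xyz[, 3, 1], 1, 0, a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atoms of an ensemble
#'
#' @param ens An `ensemble`.
#' @param chain Chain identifier(s), or NULL for all.
#' @param resid Residue indices, or NULL for all.
#' @param atom_names Atom names (e.g. `c("N","CA","C","O")`), or NULL.
#' @param elements Element symbols, or NULL. Use `heavy = TRUE` to drop
#'   hydrogens.
#' @param heavy Drop hydrogen atoms.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(ens, chain = NULL, resid = NULL, atom_names = NULL,
                         elements = NULL, heavy = FALSE) {
  a <- ens$atoms
  sel <- rep(TRUE, nrow(a))
  if (!is.null(chain)) sel <- sel & a$chain %in% chain
  if (!is.null(resid)) sel <- sel & a$residue_index %in% resid
  if (!is.null(atom_names)) sel <- sel & a$atom_name %in% atom_names
  if (!is.null(elements)) sel <- sel & a$element %in% elements
  if (heavy) sel <- sel & a$element != "H"
  which(sel)
}

# ---------------------------------------------------------------------------
# distance constraints

#' H-H distance constraints (NOE upper bounds)
#'
#' @param residue_a,atom_a,residue_b,atom_b Atom identifiers.
#' @param upper_bound Upper distance bound in Angstrom (default 5, the
#'   detection range of NOE cross peaks).
#' @param chain_a,chain_b Optional chain identifiers (default any chain).
#' @return data.frame of class `distance_constraints`.
#' @export
distance_constraints <- function(residue_a, atom_a, residue_b, atom_b,
                                 upper_bound = 5.0, chain_a = NA, chain_b = NA) {
  df <- data.frame(residue_a = as.integer(residue_a), atom_a = atom_a,
                   residue_b = as.integer(residue_b), atom_b = atom_b,
                   upper_bound = rep_len(upper_bound, length(residue_a)),
                   chain_a = rep_len(chain_a, length(residue_a)),
                   chain_b = rep_len(chain_b, length(residue_a)),
                   stringsAsFactors = FALSE)
  if (any(df$upper_bound <= 0)) stop("upper_bound must be positive")
  same <- df$residue_a == df$residue_b & df$atom_a == df$atom_b &
    (is.na(df$chain_a) | is.na(df$chain_b) | df$chain_a == df$chain_b)
  if (any(same)) stop("constraint between an atom and itself")
  class(df) <- c("distance_constraints", "data.frame")
  df
}

#' Read distance constraints from TSV
#'
#' Columns: `residue_a atom_a residue_b atom_b upper_bound` (Angstrom);
#' `#` comments allowed.
#' @param path Input file.
#' @return A `distance_constraints` table.
#' @export
read_distance_constraints <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("residue_a", "atom_a", "residue_b",
                                        "atom_b", "upper_bound"),
                          stringsAsFactors = FALSE)
  distance_constraints(df$residue_a, df$atom_a, df$residue_b, df$atom_b,
                       df$upper_bound)
}
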