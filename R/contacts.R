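# Representative-atom residue contact probabilities and up/down difference
# maps.

#' Representative side-chain heavy atom per residue type
#'
#' One heavy atom per standard residue type, used to reduce the cost of
#' contact counting: CZ of Arg, CG of His, NZ of Lys, CG of Asp, CD of Glu,
#' OG of Ser, CB of Thr, CG of Asn, CD of Gln, SG of Cys, CA of Gly, CG of
#' Pro, CB of Ala, CB of Val, CB of Ile, CG of Leu, CE of Met, CZ of Phe,
#' OH of Tyr, CE2 of Trp.
#'
#' @return named character vector mapping residue name to atom name.
#' @export
representative_atom_table <- function() {
  c(ARG = "CZ", HIS = "CG", LYS = "NZ", ASP = "CG", GLU = "CD",
    SER = "OG", THR = "CB", ASN = "CG", GLN = "CD", CYS = "SG",
    GLY = "CA", PRO = "CG", ALA = "CB", VAL = "CB", ILE = "CB",
    LEU = "CG", MET = "CE", PHE = "CZ", TYR = "OH", TRP = "CE2")
}

#' Representative atom index for one residue
#'
#' @param system a [particle_system()].
#' @param chain chain identifier.
#' @param resid residue number.
#' @param extra_table optional named character vector extending/overriding
#'   [representative_atom_table()] for non-standard residue types.
#' @return 0-based atom index of the mapped heavy atom.
#' @export
representative_atom <- function(system, chain, resid, extra_table = NULL) {
  tab <- representative_atom_table()
  if (!is.null(extra_table)) tab[names(extra_table)] <- extra_table
  rows <- which(system$chain_id == chain & system$residue_id == resid)
  if (!length(rows)) stop("residue ", chain, ":", resid, " not in system")
  rname <- toupper(system$residue_name[rows[1]])
  if (!rname %in% names(tab)) {
    stop("no representative atom mapped for residue type ", rname,
         "; supply extra_table")
  }
  hit <- rows[toupper(system$atom_name[rows]) == tab[[rname]]]
  if (length(hit) != 1) {
    stop("residue ", chain, ":", resid, " (", rname, ") lacks atom ",
         tab[[rname]])
  }
  system$atom_index[hit]
}

#' Residue-residue contact probabilities over a trajectory
#'
#' A residue pair is in contact in a frame when the minimum-image distance
#' between the two representative atoms is strictly below `cutoff`. Pairs of
#' sequence neighbours within a chain are excluded when
#' `|delta resid| < min_seq_sep`.
#'
#' @param traj a [trajectory()].
#' @param residues optional data.frame with columns `chain_id`, `residue_id`
#'   restricting the residue universe; defaults to all residues with a
#'   mapped representative atom.
#' @param cutoff contact distance in angstrom (default 5).
#' @param min_seq_sep minimum same-chain sequence separation (default 2;
#'   set 0 to disable the exclusion).
#' @param extra_table forwarded to [representative_atom()].
#' @return data.frame of class `contact_records` with columns `chain_a`,
#'   `resid_a`, `chain_b`, `resid_b`, `p`, `n_frames`; pairs canonically
#'   ordered by (chain, resid).
#' @export
contact_probability <- function(traj, residues = NULL, cutoff = 5,
                                min_seq_sep = 2, extra_table = NULL) {
  stopifnot(cutoff > 0)
  sys <- traj$system
  if (is.null(residues)) {
    residues <- unique(sys[, c("chain_id", "residue_id")])
    mapped <- toupper(sys$residue_name[match(
      paste(residues$chain_id, residues$residue_id),
      paste(sys$chain_id, sys$residue_id))]) %in%
      names(representative_atom_table())
    if (!is.null(extra_table)) {
      mapped <- mapped | toupper(sys$residue_name[match(
        paste(residues$chain_id, residues$residue_id),
        paste(sys$chain_id, sys$residue_id))]) %in% toupper(names(extra_table))
    }
    residues <- residues[mapped, , drop = FALSE]
  }
  residues <- residues[order(residues$chain_id, residues$residue_id), ,
                       drop = FALSE]
  nres <- nrow(residues)
  rep_idx <- mapply(representative_atom,
                    chain = residues$chain_id, resid = residues$residue_id,
                    MoreArgs = list(system = sys, extra_table = extra_table))
  nf <- n_frames(traj)
  hits <- matrix(0L, nres, nres)
  for (f in seq_len(nf)) {
    xyz <- matrix(traj$coords[rep_idx + 1L, , f], ncol = 3)
    box <- traj$box[, f]
    d2 <- matrix(0, nres, nres)
    for (k in 1:3) {
      dk <- min_image(outer(xyz[, k], xyz[, k], "-"), box[k])
      d2 <- d2 + dk^2
    }
    hits <- hits + (d2 < cutoff^2)
  }
  ia <- rep(seq_len(nres), nres)
  ib <- rep(seq_len(nres), each = nres)
  keep <- ia < ib
  ia <- ia[keep]; ib <- ib[keep]
  same_chain <- residues$chain_id[ia] == residues$chain_id[ib]
  near <- same_chain &
    abs(residues$residue_id[ia] - residues$residue_id[ib]) < min_seq_sep
  ia <- ia[!near]; ib <- ib[!near]
  out <- data.frame(
    chain_a = residues$chain_id[ia], resid_a = residues$residue_id[ia],
    chain_b = residues$chain_id[ib], resid_b = residues$residue_id[ib],
    p = hits[cbind(ia, ib)] / nf, n_frames = rep(nf, length(ia))
  )
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_records", "data.frame")
  out
}

pair_key <- function(df, a = c("chain_a", "resid_a"),
                     b = c("chain_b", "resid_b")) {
  paste(df[[a[1]]], df[[a[2]]], df[[b[1]]], df[[b[2]]], sep = "|")
}

#' Contact difference map between two states
#'
#' Joins two contact-record sets over the union of their pair universes
#' (absent pairs contribute p = 0), takes `dp = p_up - p_down`, and retains
#' pairs with `|dp|` strictly above `threshold`. Retained pairs are classed
#' inter-chain when the two chain identifiers differ.
#'
#' @param up,down [contact_probability()] results.
#' @param threshold retention threshold on `|dp|` (default 0.25).
#' @return data.frame of class `contact_difference_map` with columns
#'   `chain_a`, `resid_a`, `chain_b`, `resid_b`, `p_up`, `p_down`, `dp`,
#'   `class`; retention counts (`n_total`, `n_inter`, `n_intra`) travel as
#'   attributes.
#' @export
difference_map <- function(up, down, threshold = 0.25) {
  ku <- pair_key(up)
  kd <- pair_key(down)
  keys <- union(ku, kd)
  pu <- up$p[match(keys, ku)]
  pd <- down$p[match(keys, kd)]
  pu[is.na(pu)] <- 0
  pd[is.na(pd)] <- 0
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  out <- data.frame(
    chain_a = parts[, 1], resid_a = as.integer(parts[, 2]),
    chain_b = parts[, 3], resid_b = as.integer(parts[, 4]),
    p_up = pu, p_down = pd, dp = pu - pd
  )
  out <- out[abs(out$dp) > threshold, , drop = FALSE]
  out$class <- ifelse(out$chain_a == out$chain_b, "intra-chain", "inter-chain")
  out <- out[order(-abs(out$dp)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "n_total") <- nrow(out)
  attr(out, "n_inter") <- sum(out$class == "inter-chain")
  attr(out, "n_intra") <- sum(out$class == "intra-chain")
  class(out) <- c("contact_difference_map", "data.frame")
  out
}
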