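#' Select atoms by expression
#'
#' Small selection grammar modelled on the usual MD analysis toolkits.
#' Clauses are joined with `and`; each clause is a keyword followed by one or
#' more values:
#' \itemize{
#'   \item `chain A` — chain identifier(s)
#'   \item `resid 315-333`, `resid 5`, `resid 4 7 9` — residue id(s)/range(s)
#'   \item `resname ARG LYS` — residue name(s)
#'   \item `name CA` — atom name(s)
#'   \item `element K` — element symbol(s)
#'   \item `backbone` — protein backbone atoms (N, CA, C, O)
#' }
#'
#' @param system a [particle_system()].
#' @param expression selection string, e.g.
#'   `"chain A and resid 315-333 and name CA"`.
#' @return sorted, duplicate-free integer vector of 0-based atom indices.
#'   An empty selection returns `integer(0)` with a warning.
#' @export
select_atoms <- function(system, expression) {
  stopifnot(inherits(system, "particle_system"))
  clauses <- strsplit(trimws(expression), "\\s+and\\s+")[[1]]
  keep <- rep(TRUE, nrow(system))
  for (clause in clauses) {
    toks <- strsplit(trimws(clause), "\\s+")[[1]]
    if (!length(toks)) next
    kw <- tolower(toks[1])
    vals <- toks[-1]
    keep <- keep & switch(kw,
      chain = system$chain_id %in% vals,
      resid = system$residue_id %in% expand_resid(vals, clause),
      resname = toupper(system$residue_name) %in% toupper(vals),
      name = toupper(system$atom_name) %in% toupper(vals),
      element = toupper(system$element) %in% toupper(vals),
      backbone = toupper(system$atom_name) %in% c("N", "CA", "C", "O"),
      stop("unknown selection keyword '", kw, "' in clause '", clause, "'")
    )
  }
  idx <- system$atom_index[keep]
  if (!length(idx)) warning("selection '", expression, "' matched no atoms")
  sort(unique(idx))
}

expand_resid <- function(vals, clause) {
  if (!length(vals)) stop("resid clause needs values: '", clause, "'")
  out <- integer(0)
  for (v in vals) {
    if (grepl("^-?[0-9]+--?[0-9]+$", v) && grepl("-", substring(v, 2))) {
      parts <- regmatches(v, regexec("^(-?[0-9]+)-(-?[0-9]+)$", v))[[1]]
      out <- c(out, seq(as.integer(parts[2]), as.integer(parts[3])))
    } else if (grepl("^-?[0-9]+$", v)) {
      out <- c(out, as.integer(v))
    } else {
      stop("unparsable resid value '", v, "' in clause '", clause, "'")
    }
  }
  out
}
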