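#' A charge-annotated structure with one or more coordinate frames
#'
#' Atoms (names, residues, partial charges in elementary units) shared by a
#' list of coordinate snapshots (n x 3 matrices, angstrom), plus named atom
#' selections used as exclusion sets in potential sums.
#'
#' @param atoms data.frame with columns `name`, `resname`, `resid`, `chain`,
#'   `charge`.
#' @param snapshots list of numeric n x 3 coordinate matrices, one per frame.
#' @param selections named list of integer index vectors into `atoms`.
#' @return object of class `charge_system`.
#' @export
charge_system <- function(atoms, snapshots, selections = list()) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "resname", "resid", "chain", "charge") %in%
                  names(atoms)),
            all(nzchar(atoms$name)),
            is.numeric(atoms$charge), all(is.finite(atoms$charge)),
            is.list(snapshots), length(snapshots) >= 1L)
  n <- nrow(atoms)
  for (s in snapshots) {
    stopifnot(is.matrix(s), ncol(s) == 3L, nrow(s) == n, all(is.finite(s)))
  }
  if (length(selections)) {
    stopifnot(!is.null(names(selections)), all(nzchar(names(selections))))
    for (sel in selections)
      stopifnot(all(sel >= 1L), all(sel <= n))
  }
  structure(list(atoms = atoms, snapshots = snapshots,
                 selections = selections),
            class = "charge_system")
}

#' @export
print.charge_system <- function(x, ...) {
  cat(sprintf("charge system: %d atoms, %d frame(s), total charge %+.3f e\n",
              nrow(x$atoms), length(x$snapshots), sum(x$atoms$charge)))
  if (length(x$selections))
    cat("  selections:", paste(names(x$selections), collapse = ", "), "\n")
  invisible(x)
}

# resolve an exclusion argument (NULL, selection name, or index vector)
.resolve_exclusion <- function(system, exclude) {
  if (is.null(exclude) || identical(exclude, "none")) return(integer(0))
  if (is.character(exclude)) {
    if (!exclude %in% names(system$selections))
      stop("unknown selection: ", exclude, call. = FALSE)
    return(system$selections[[exclude]])
  }
  as.integer(exclude)
}

#' Read a PQR file into a charge system
#'
#' Whitespace-delimited PQR records
#' (`ATOM serial name resname [chain] resid x y z charge radius`); the radius
#' column is parsed and discarded. Multi-`MODEL` files become multiple
#' snapshots sharing the first model's atom annotations.
#'
#' @param path PQR file path.
#' @param selections optional named list of selections passed through.
#' @return a [charge_system()].
#' @export
read_pqr <- function(path, selections = list()) {
  lines <- readLines(path)
  models <- .split_models(lines)
  parse_model <- function(ml, which_model) {
    recs <- ml[grepl("^(ATOM|HETATM)", ml)]
    if (!length(recs)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
    rows <- lapply(seq_along(recs), function(i) {
      tok <- strsplit(trimws(recs[[i]]), "\\s+")[[1]]
      # with or without a chain column: 10 or 11 tokens
      if (length(tok) == 11L) {
        out <- list(name = tok[3], resname = tok[4], chain = tok[5],
                    resid = tok[6], x = tok[7], y = tok[8], z = tok[9],
                    charge = tok[10])
      } else if (length(tok) == 10L) {
        out <- list(name = tok[3], resname = tok[4], chain = "",
                    resid = tok[5], x = tok[6], y = tok[7], z = tok[8],
                    charge = tok[9])
      } else {
        stop(sprintf("malformed PQR record (model %d, record %d): %s",
                     which_model, i, recs[[i]]), call. = FALSE)
      }
      num <- suppressWarnings(as.numeric(out[c("x", "y", "z", "charge")]))
      if (any(is.na(num)))
        stop(sprintf("non-numeric coordinate/charge (model %d, record %d): %s",
                     which_model, i, recs[[i]]), call. = FALSE)
      out
    })
    rows
  }
  first <- parse_model(models[[1]], 1L)
  atoms <- data.frame(
    name = vapply(first, `[[`, "", "name"),
    resname = vapply(first, `[[`, "", "resname"),
    resid = as.integer(vapply(first, `[[`, "", "resid")),
    chain = vapply(first, `[[`, "", "chain"),
    charge = as.numeric(vapply(first, `[[`, "", "charge"))
  )
  snaps <- lapply(seq_along(models), function(k) {
    rows <- parse_model(models[[k]], k)
    if (length(rows) != nrow(atoms))
      stop("model ", k, " has a different atom count", call. = FALSE)
    m <- t(vapply(rows, function(r)
      as.numeric(c(r$x, r$y, r$z)), numeric(3)))
    dimnames(m) <- NULL
    m
  })
  charge_system(atoms, snaps, selections)
}

# split raw lines into per-MODEL chunks (single chunk when no MODEL records)
.split_models <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (!length(starts)) return(list(lines))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts))
    stop("unbalanced MODEL/ENDMDL records", call. = FALSE)
  Map(function(s, e) lines[(s + 1L):(e - 1L)], starts, ends)
}

#' Read a (multi-model) PDB plus a charge table into a charge system
#'
#' Fixed-column PDB ATOM/HETATM parsing; partial charges are looked up in a
#' companion CSV with columns `resname`, `name`, `charge` keyed by residue
#' and atom name. Atoms without a charge mapping abort with a message listing
#' every offender. `MODEL` blocks become snapshots.
#'
#' @param path PDB file path.
#' @param charge_table data.frame or CSV path with `resname`, `name`,
#'   `charge` columns.
#' @param selections optional named selections passed through.
#' @return a [charge_system()].
#' @export
read_pdb_charges <- function(path, charge_table, selections = list()) {
  if (is.character(charge_table))
    charge_table <- utils::read.csv(charge_table, strip.white = TRUE)
  stopifnot(all(c("resname", "name", "charge") %in% names(charge_table)))
  lines <- readLines(path)
  models <- .split_models(lines)
  parse_model <- function(ml, which_model) {
    idx <- grep("^(ATOM  |HETATM)", ml)
    if (!length(idx)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
    recs <- ml[idx]
    sub_col <- function(s, a, b) trimws(substring(s, a, b))
    d <- data.frame(
      name = sub_col(recs, 13, 16),
      resname = sub_col(recs, 18, 20),
      chain = sub_col(recs, 22, 22),
      resid = suppressWarnings(as.integer(sub_col(recs, 23, 26))),
      x = suppressWarnings(as.numeric(sub_col(recs, 31, 38))),
      y = suppressWarnings(as.numeric(sub_col(recs, 39, 46))),
      z = suppressWarnings(as.numeric(sub_col(recs, 47, 54)))
    )
    bad <- which(is.na(d$x) | is.na(d$y) | is.na(d$z) | is.na(d$resid))
    if (length(bad))
      stop("malformed PDB records at line(s): ",
           paste(idx[bad], collapse = ", "), call. = FALSE)
    d
  }
  d1 <- parse_model(models[[1]], 1L)
  key <- paste(d1$resname, d1$name)
  map <- stats::setNames(charge_table$charge,
                         paste(charge_table$resname, charge_table$name))
  charge <- unname(map[key])
  if (anyNA(charge)) {
    offenders <- unique(key[is.na(charge)])
    stop("no charge mapping for atom(s): ",
         paste(offenders, collapse = "; "), call. = FALSE)
  }
  atoms <- data.frame(name = d1$name, resname = d1$resname, resid = d1$resid,
                      chain = d1$chain, charge = charge)
  snaps <- lapply(seq_along(models), function(k) {
    dk <- parse_model(models[[k]], k)
    if (nrow(dk) != nrow(atoms))
      stop("model ", k, " has a different atom count", call. = FALSE)
    unname(as.matrix(dk[, c("x", "y", "z")]))
  })
  charge_system(atoms, snaps, selections)
}

#' Coulomb potential at a point from a charge system
#'
#' Direct pairwise sum \eqn{V(R) = k_C \sum_{i \notin S} q_i / |R - r_i|}
#' with \eqn{k_C} = 14.3996 V angstrom / e; no distance cutoff and no
#' periodic images. Included atoms closer than 1e-6 angstrom to the
#' evaluation point raise an error (self-interaction / clash).
#'
#' @param point length-3 coordinates, angstrom.
#' @param system a [charge_system()].
#' @param frame snapshot index (default 1).
#' @param exclude selection name, index vector, or NULL.
#' @return potential in volts.
#' @examples
#' sys <- charge_system(
#'   data.frame(name = "Q", resname = "ION", resid = 1L, chain = "",
#'              charge = 1),
#'   list(matrix(c(0, 0, 0), 1)))
#' potential_at(c(1, 0, 0), sys)  # 14.3996 V
#' @export
potential_at <- function(point, system, frame = 1L, exclude = NULL) {
  stopifnot(inherits(system, "charge_system"), length(point) == 3L,
            all(is.finite(point)),
            frame >= 1L, frame <= length(system$snapshots))
  excl <- .resolve_exclusion(system, exclude)
  keep <- setdiff(seq_len(nrow(system$atoms)), excl)
  if (!length(keep)) return(0)
  xyz <- system$snapshots[[frame]][keep, , drop = FALSE]
  q <- system$atoms$charge[keep]
  d2 <- (xyz[, 1] - point[1])^2 + (xyz[, 2] - point[2])^2 +
    (xyz[, 3] - point[3])^2
  if (any(d2 < 1e-12))
    stop("included atom within 1e-6 A of the evaluation point", call. = FALSE)
  .kcoul_v_ang * sum(q / sqrt(d2))
}

# locate chain atoms (by atom name) in the system; errors on missing/ambiguous
.chain_indices <- function(system, atom_names) {
  vapply(atom_names, function(nm) {
    i <- which(system$atoms$name == nm)
    if (!length(i)) stop("chain atom not found: ", nm, call. = FALSE)
    if (length(i) > 1L)
      stop("chain atom name is ambiguous: ", nm, call. = FALSE)
    i
  }, integer(1))
}

#' Project the charge-transfer chain onto the molecular axis
#'
#' Projects each chain atom onto the line through the `axis_from` ->
#' `axis_to` atoms and evaluates the Coulomb potential at the atoms' true
#' positions. The returned `distance` is the *signed* projection coordinate
#' along the axis direction, with the first chain atom at 0; for chain atoms
#' listed in axis order this reduces to cumulative distances 0, d1, d1+d2,
#' ....
#'
#' @param system a [charge_system()].
#' @param frame snapshot index.
#' @param axis_from,axis_to atom names defining the axis (defaults CA2 ->
#'   CE2, the charge-transfer +x direction).
#' @param chain_atoms atom names whose potentials are sampled (default the
#'   phenolate-to-bridge carbons CE2, CD2, CG2, CB2, CA2).
#' @param exclude selection name / indices excluded from the potential sum.
#' @return data.frame with `atom`, `distance` (angstrom, signed along the
#'   axis), `potential` (V).
#' @export
project_chain <- function(system, frame = 1L, axis_from = "CA2",
                          axis_to = "CE2",
                          chain_atoms = c("CE2", "CD2", "CG2", "CB2", "CA2"),
                          exclude = NULL) {
  stopifnot(inherits(system, "charge_system"))
  xyz <- system$snapshots[[frame]]
  i_from <- .chain_indices(system, axis_from)
  i_to <- .chain_indices(system, axis_to)
  u <- xyz[i_to, ] - xyz[i_from, ]
  L <- sqrt(sum(u^2))
  if (L < 1e-9) stop("axis atoms coincide", call. = FALSE)
  u <- u / L
  idx <- .chain_indices(system, chain_atoms)
  t_coord <- as.numeric((xyz[idx, , drop = FALSE] %*% u))
  s <- t_coord - t_coord[1]
  pot <- vapply(idx, function(i)
    potential_at(xyz[i, ], system, frame = frame, exclude = exclude),
    numeric(1))
  data.frame(atom = chain_atoms, distance = s, potential = pot)
}

#' Projected electric field from the potential gradient along the axis
#'
#' Per snapshot, the Coulomb potentials at the chain atoms are regressed
#' (unweighted OLS) on their signed axis coordinates; the field is the
#' negative slope converted V/angstrom -> MV/cm (x100). The sign convention
#' is the projection on the `axis_from` -> `axis_to` (CA2 -> CE2, +x)
#' direction. Results are averaged over snapshots with the population SD.
#'
#' @inheritParams project_chain
#' @return object of class `axis_field`: `mean`, `sd` (MV/cm),
#'   `per_snapshot` (per-frame fields), `r2` (per-frame coefficient of
#'   determination; `NA` when the potentials are constant), `intercept`
#'   (mean, V), `n_frames`.
#' @export
axis_field <- function(system, exclude = NULL, axis_from = "CA2",
                       axis_to = "CE2",
                       chain_atoms = c("CE2", "CD2", "CG2", "CB2", "CA2")) {
  stopifnot(inherits(system, "charge_system"), length(chain_atoms) >= 2L)
  nf <- length(system$snapshots)
  slopes <- numeric(nf)
  r2 <- numeric(nf)
  icept <- numeric(nf)
  for (k in seq_len(nf)) {
    pc <- project_chain(system, frame = k, axis_from = axis_from,
                        axis_to = axis_to, chain_atoms = chain_atoms,
                        exclude = exclude)
    if (stats::sd(pc$distance) == 0)
      stop("degenerate regression: chain atoms project to one point",
           call. = FALSE)
    fit <- stats::lm(potential ~ distance, data = pc)
    slopes[k] <- stats::coef(fit)[[2]]
    icept[k] <- stats::coef(fit)[[1]]
    tss <- sum((pc$potential - mean(pc$potential))^2)
    r2[k] <- if (tss < .Machine$double.eps) NA_real_ else
      1 - sum(stats::residuals(fit)^2) / tss
  }
  fields <- -slopes * 100  # V/A -> MV/cm
  structure(
    list(mean = mean(fields),
         sd = sqrt(mean((fields - mean(fields))^2)),
         per_snapshot = fields, r2 = r2, intercept = mean(icept),
         n_frames = nf, axis = c(from = axis_from, to = axis_to)),
    class = "axis_field"
  )
}

#' @export
print.axis_field <- function(x, ...) {
  cat(sprintf("projected field (%s -> %s): %+.3f MV/cm (sd %.3f over %d frame(s))\n",
              x$axis[["from"]], x$axis[["to"]], x$mean, x$sd, x$n_frames))
  invisible(x)
}

#' Mean and fluctuation of the projected field over snapshots
#'
#' Arithmetic mean and population standard deviation (denominator n) of the
#' per-frame field projections of an [axis_field()] result.
#'
#' @param result an `axis_field` object.
#' @return list with `mean` and `sd`, MV/cm.
#' @export
snapshot_statistics <- function(result) {
  stopifnot(inherits(result, "axis_field"))
  f <- result$per_snapshot
  list(mean = mean(f), sd = sqrt(mean((f - mean(f))^2)))
}
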