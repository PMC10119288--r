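# The 36 fragment-peak types: b/y series, nine neutral-loss classes, fragment
# charge 1 or 2. Loss classes: "" none, o = -H2O, n = -NH3, p = -H3PO4,
# op = -H2O-H3PO4, np = -NH3-H3PO4, 2p = -2xH3PO4, o2p = -H2O-2xH3PO4,
# n2p = -NH3-2xH3PO4.

.fragment_types_cache <- new.env(parent = emptyenv())

.build_fragment_types <- function() {
  tiers <- list(c("", "n", "o"), c("p", "np", "op"), c("2p", "n2p", "o2p"))
  rows <- list()
  for (tier in tiers) {
    for (series in c("b", "y")) {
      for (z in 1:2) {
        for (loss in tier) {
          rows[[length(rows) + 1L]] <- data.frame(
            label = paste0(series, loss, z), series = series, loss = loss,
            frag_charge = z,
            n_h2o = as.integer(grepl("o", loss)),
            n_nh3 = as.integer(grepl("n", loss)),
            n_phospho_loss = if (grepl("2p", loss)) 2L else as.integer(grepl("p", loss)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$loss_mass <- out$n_h2o * .H2O + out$n_nh3 * .NH3 + out$n_phospho_loss * .H3PO4
  rownames(out) <- NULL
  out
}

.fragment_types_table <- function() {
  if (is.null(.fragment_types_cache$tab))
    .fragment_types_cache$tab <- .build_fragment_types()
  .fragment_types_cache$tab
}

#' Enumerate the 36 fragment-peak types
#'
#' All combinations of ion series (b, y), neutral-loss class (none, -NH3,
#' -H2O, and the phosphoric-acid losses -H3PO4, -NH3-H3PO4, -H2O-H3PO4,
#' -2H3PO4, -NH3-2H3PO4, -H2O-2H3PO4) and fragment charge (1, 2), in the
#' fixed canonical order (b1, bn1, bo1, b2, bn2, bo2, y1, ..., yo2p2) so
#' intensity vectors from different sources are comparable.
#'
#' @return Data frame with 36 rows and columns `label`, `series`, `loss`,
#'   `frag_charge`, `n_h2o`, `n_nh3`, `n_phospho_loss`, `loss_mass`.
#' @export
fragment_types <- function() .fragment_types_table()

#' Theoretical fragment ions of a peptidoform
#'
#' Computes m/z for every feasible (fragment type, cleavage index) pair.
#' A b ion at cleavage index k contains the k N-terminal residues (plus any
#' N-terminal modification); a y ion the k C-terminal residues plus water.
#' Neutral-loss classes removing more phosphate groups than the fragment
#' contains are infeasible and omitted, as are fragments whose neutral mass
#' after loss would be non-positive. Water/ammonia losses are emitted for
#' every fragment.
#'
#' @param p A [peptidoform].
#' @return Data frame ordered by cleavage index (major) then type (minor)
#'   with columns `label`, `series`, `loss`, `frag_charge`, `cleavage`,
#'   `mz`, `frag_nphospho`.
#' @export
theoretical_spectrum <- function(p) {
  core <- .theo_core(p)
  ft <- .fragment_types_table()
  out <- data.frame(
    label = ft$label[core$ti], series = ft$series[core$ti],
    loss = ft$loss[core$ti], frag_charge = ft$frag_charge[core$ti],
    cleavage = core$cleavage, mz = core$mz,
    frag_nphospho = core$frag_nphospho, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# vector core of theoretical_spectrum, used in scoring loops: feasible ions
# only, cleavage-major / type-minor order
.theo_core <- function(p) {
  L <- nchar(p$sequence)
  if (L < 2L) stop("peptide must have at least 2 residues")
  m <- position_masses(p)
  nterm <- attr(m, "nterm")
  k <- seq_len(L - 1L)
  bmass <- cumsum(m)[k] + nterm
  tail_sums <- rev(cumsum(rev(m)))            # tail_sums[i] = sum(m[i:L])
  ymass <- tail_sums[L + 1L - k] + .H2O       # ymass[k] = sum of last k residues + H2O
  is_ph <- integer(L)
  is_ph[phospho_positions(p)] <- 1L
  bph <- cumsum(is_ph)[k]
  yph <- sum(is_ph) - cumsum(is_ph)[L - k]
  ft <- .fragment_types_table()
  nt <- nrow(ft)
  kk <- rep(k, each = nt)
  ti <- rep.int(seq_len(nt), L - 1L)
  sb <- ft$series[ti] == "b"
  neutral <- ymass[kk]; neutral[sb] <- bmass[kk[sb]]
  neutral <- neutral - ft$loss_mass[ti]
  nph <- yph[kk]; nph[sb] <- bph[kk[sb]]
  feas <- nph >= ft$n_phospho_loss[ti] & neutral > 0
  z <- ft$frag_charge[ti]
  list(ti = ti[feas], cleavage = kk[feas],
       mz = ((neutral + z * .PROTON) / z)[feas],
       series_b = sb[feas], frag_nphospho = nph[feas], length = L)
}

#' m/z of a single fragment ion
#'
#' @param p A [peptidoform].
#' @param type Fragment-type label (e.g. `"b1"`, `"yp2"`) or a one-row
#'   subset of [fragment_types()].
#' @param cleavage Cleavage index k, 1 <= k <= length - 1 (number of
#'   N-terminal residues for b ions, C-terminal residues for y ions).
#' @return List with elements `mz` (Th; NA when infeasible) and `feasible`.
#' @examples
#' fragment_mz(peptidoform("AG", charge = 1), "b1", 1)  # 72.0444
#' @export
fragment_mz <- function(p, type, cleavage) {
  L <- nchar(p$sequence)
  if (cleavage < 1L || cleavage > L - 1L) stop("cleavage index out of range")
  if (is.character(type)) {
    ft <- .fragment_types_table()
    row <- ft[ft$label == type, , drop = FALSE]
    if (!nrow(row)) stop("unknown fragment type label: ", type)
  } else row <- as.data.frame(type)
  ts <- theoretical_spectrum(p)
  hit <- ts[ts$label == row$label & ts$cleavage == cleavage, , drop = FALSE]
  if (nrow(hit)) list(mz = hit$mz[1L], feasible = TRUE)
  else list(mz = NA_real_, feasible = FALSE)
}
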