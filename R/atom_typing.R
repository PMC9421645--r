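## Pharmacophoric atom typing.
##
## Protein atoms are typed by residue-template lookup (standard amino acids
## plus metal cofactors); ligand atoms are typed from connectivity inferred
## from interatomic distances, since fragment-screen PDB files carry neither
## hydrogens nor bond records. Detection downstream is heavy-atom based.

WATER_RESNAMES  <- c("HOH", "WAT", "DOD", "H2O", "TIP", "SOL")

## common cryoprotectants / buffer components excluded from the protein side
BUFFER_RESNAMES <- c("EDO", "GOL", "PEG", "PG4", "P6G", "DMS", "ACT", "FMT",
                     "SO4", "PO4", "EPE", "MES", "TRS", "CIT", "BME", "MPD",
                     "IMD", "NO3", "CL", "BR", "IOD", "NH4")

METAL_ELEMENTS <- c("ZN", "MG", "MN", "FE", "CU", "NI", "CO", "NA", "K",
                    "CA", "CD", "MO", "LI")

## single-bond covalent radii (Angstrom) for bond inference on the ligand
COVALENT_RADII <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                    F = 0.57, P = 1.07, S = 1.05, CL = 1.02, SE = 1.20,
                    BR = 1.20, I = 1.39)

## ---- protein residue templates -------------------------------------------
## For every standard residue: which side-chain atoms are hydrophobic,
## H-bond donors/acceptors, formally charged, and which atom names form
## aromatic rings. Backbone N (donor, except Pro) and O/OXT (acceptor) are
## handled generically; ring/imidazole carbons bonded to nitrogen are not
## counted hydrophobic.
protein_templates <- function() {
  t <- list(
    ALA = list(hphob = "CB"),
    ARG = list(hphob = c("CB", "CG"), donor = c("NE", "NH1", "NH2"),
               positive = "CZ"),
    ASN = list(hphob = "CB", donor = "ND2", acceptor = "OD1"),
    ASP = list(hphob = "CB", acceptor = c("OD1", "OD2"),
               negative = c("OD1", "OD2")),
    CYS = list(hphob = c("CB", "SG")),
    GLN = list(hphob = c("CB", "CG"), donor = "NE2", acceptor = "OE1"),
    GLU = list(hphob = c("CB", "CG"), acceptor = c("OE1", "OE2"),
               negative = c("OE1", "OE2")),
    GLY = list(),
    HIS = list(hphob = "CB", donor = "NE2", acceptor = "ND1",
               rings = list(c("CG", "ND1", "CE1", "NE2", "CD2"))),
    ILE = list(hphob = c("CB", "CG1", "CG2", "CD1")),
    LEU = list(hphob = c("CB", "CG", "CD1", "CD2")),
    LYS = list(hphob = c("CB", "CG", "CD"), donor = "NZ", positive = "NZ"),
    MET = list(hphob = c("CB", "CG", "SD", "CE")),
    PHE = list(hphob = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
               rings = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"))),
    PRO = list(hphob = c("CB", "CG", "CD")),
    SER = list(donor = "OG", acceptor = "OG"),
    THR = list(hphob = "CG2", donor = "OG1", acceptor = "OG1"),
    TRP = list(hphob = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
               donor = "NE1",
               rings = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
                            c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))),
    TYR = list(hphob = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
               donor = "OH", acceptor = "OH",
               rings = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"))),
    VAL = list(hphob = c("CB", "CG1", "CG2"))
  )
  t
}

## type the protein-side rows of an atom table; returns the table with the
## flag columns filled in. Unknown residues fall back to element rules.
type_protein_atoms <- function(atoms) {
  tmpl <- protein_templates()
  prot <- which(!atoms$is_ligand)
  unknown <- character(0)
  for (i in prot) {
    el <- toupper(atoms$element[i])
    if (el %in% METAL_ELEMENTS) {
      atoms$is_metal[i] <- TRUE
      atoms$charge[i] <- "+"
      next
    }
    rn <- atoms$resname[i]; an <- atoms$name[i]
    tp <- tmpl[[rn]]
    if (is.null(tp)) {
      ## element-level fallback for non-standard residues
      unknown <- c(unknown, rn)
      if (el == "O") atoms$acceptor[i] <- TRUE
      if (el == "N") atoms$donor[i] <- TRUE
      next
    }
    if (an == "N" && rn != "PRO") atoms$donor[i] <- TRUE
    if (an %in% c("O", "OXT")) atoms$acceptor[i] <- TRUE
    if (an %in% tp$hphob) atoms$hydrophobic[i] <- TRUE
    if (an %in% tp$donor) atoms$donor[i] <- TRUE
    if (an %in% tp$acceptor) atoms$acceptor[i] <- TRUE
    if (an %in% tp$positive) atoms$charge[i] <- "+"
    if (an %in% tp$negative) atoms$charge[i] <- "-"
    if (!is.null(tp$rings) && an %in% unlist(tp$rings))
      atoms$aromatic[i] <- TRUE
  }
  if (length(unknown))
    message("atom typing: element-level fallback for residue(s) ",
            paste(unique(unknown), collapse = ", "))
  atoms
}

## infer a bond list (2-column index matrix) among the given atom rows from
## covalent radii; indices refer to rows of `atoms`
infer_bonds <- function(atoms, rows) {
  n <- length(rows)
  if (n < 2) return(matrix(integer(0), 0, 2))
  xyz <- as.matrix(atoms[rows, c("x", "y", "z")])
  rad <- COVALENT_RADII[toupper(atoms$element[rows])]
  rad[is.na(rad)] <- 1.3
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(rad, rad, "+") + 0.45
  hit <- which(d > 0.4 & d <= thr & upper.tri(d), arr.ind = TRUE)
  cbind(rows[hit[, 1]], rows[hit[, 2]])
}

## enumerate simple cycles of length 5 or 6 in a bond graph given as an
## adjacency list keyed by atom row index; returns list of sorted index sets
find_small_cycles <- function(adj, nodes) {
  seen <- new.env(parent = emptyenv())
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    for (nb in adj[[as.character(last)]]) {
      if (nb == path[1] && length(path) >= 5) {
        key <- paste(sort(path), collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          out[[length(out) + 1]] <<- sort(path)
        }
      } else if (!(nb %in% path) && length(path) < 6 && nb > path[1]) {
        walk(c(path, nb))
      }
    }
  }
  for (v in nodes) walk(v)
  out
}

## type the ligand rows from inferred connectivity. Rules (heavy-atom,
## hydrogen-free):
##  * C/S with no N/O/P/F neighbour -> hydrophobic (Cl/Br/I also hydrophobic)
##  * O, 1 heavy neighbour: acceptor + donor (carbonyl/hydroxyl ambiguous
##    without H), unless carboxylate/phosphate/sulfate-like -> negative
##    acceptor only
##  * O, 2 neighbours (ether/ester): acceptor
##  * aromatic-ring N, degree 2: acceptor; degree 3: donor (pyrrole-like)
##  * non-ring N: degree 1 acceptor; degree 2 donor+acceptor; degree 3
##    donor, and positive when all neighbours are carbons that carry no
##    carbonyl oxygen (basic amine vs amide); degree 4: positive only
type_ligand_atoms <- function(atoms) {
  lig <- which(atoms$is_ligand)
  if (!length(lig)) return(list(atoms = atoms, rings = list()))
  bonds <- infer_bonds(atoms, lig)
  adj <- new.env(parent = emptyenv())
  for (i in lig) assign(as.character(i), integer(0), envir = adj)
  if (nrow(bonds)) for (k in seq_len(nrow(bonds))) {
    a <- bonds[k, 1]; b <- bonds[k, 2]
    assign(as.character(a), c(get(as.character(a), adj), b), adj)
    assign(as.character(b), c(get(as.character(b), adj), a), adj)
  }
  nbrs <- function(i) get(as.character(i), adj)
  el <- function(i) toupper(atoms$element[i])
  deg <- function(i) length(nbrs(i))
  bond_len <- function(i, j)
    vec_norm(as.numeric(atoms[i, c("x", "y", "z")]) -
             as.numeric(atoms[j, c("x", "y", "z")]))

  ## aromatic rings: planar 5/6-cycles of C/N/O/S
  adj_list <- as.list(adj)
  rings <- find_small_cycles(adj_list, lig)
  rings <- Filter(function(r) {
    if (!all(el(r) %in% c("C", "N", "O", "S"))) return(FALSE)
    xyz <- as.matrix(atoms[r, c("x", "y", "z")])
    ls_plane(xyz)$rms < 0.15
  }, rings)
  ring_members <- unique(unlist(rings))

  for (i in lig) {
    e <- el(i)
    nb <- nbrs(i)
    if (e %in% METAL_ELEMENTS) {
      atoms$is_metal[i] <- TRUE; atoms$charge[i] <- "+"
      next
    }
    in_ring <- i %in% ring_members
    if (in_ring) atoms$aromatic[i] <- TRUE
    if (e %in% c("C", "S")) {
      if (!any(el(nb) %in% c("N", "O", "P", "F")))
        atoms$hydrophobic[i] <- TRUE
    } else if (e %in% c("CL", "BR", "I")) {
      atoms$hydrophobic[i] <- TRUE
    } else if (e == "O") {
      atoms$acceptor[i] <- TRUE
      if (length(nb) <= 1) {
        carboxylate <- FALSE
        if (length(nb) == 1 && el(nb) %in% c("C", "P", "S")) {
          term_o <- sum(vapply(nbrs(nb), function(j)
            el(j) == "O" && deg(j) == 1, logical(1)))
          carboxylate <- term_o >= 2
        }
        if (carboxylate) atoms$charge[i] <- "-"
        else atoms$donor[i] <- TRUE
      }
    } else if (e == "N") {
      amide <- any(vapply(nb, function(j) {
        el(j) == "C" && any(vapply(nbrs(j), function(k)
          el(k) == "O" && bond_len(j, k) <= 1.30, logical(1)))
      }, logical(1)))
      if (in_ring) {
        if (deg(i) <= 2) atoms$acceptor[i] <- TRUE else atoms$donor[i] <- TRUE
      } else if (deg(i) == 1) {
        ## nitrile N (short triple bond) accepts; amine-like N donates
        if (length(nb) && bond_len(i, nb[1]) <= 1.25) {
          atoms$acceptor[i] <- TRUE
        } else {
          atoms$donor[i] <- TRUE
          if (!amide && all(el(nb) == "C")) atoms$charge[i] <- "+"
        }
      } else if (deg(i) == 0) {
        atoms$acceptor[i] <- TRUE
      } else if (deg(i) == 2) {
        atoms$donor[i] <- TRUE; atoms$acceptor[i] <- TRUE
      } else if (deg(i) == 3) {
        atoms$donor[i] <- TRUE
        if (!amide && all(el(nb) == "C")) atoms$charge[i] <- "+"
      } else {
        atoms$charge[i] <- "+"
        atoms$donor[i] <- FALSE
      }
    }
  }
  list(atoms = atoms, rings = rings)
}
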