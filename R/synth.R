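# Synthetic fixture generator: plants protein families with controlled
# sequence identity, per-family domain architectures, and gene neighborhoods
# with a conserved neighbor at a controlled frequency, so the whole
# classification pipeline can be exercised against known ground truth.

#' Default per-family architecture table
#'
#' One row per planted family, mirroring the six Lhr groups: the helicase
#' core (DEAD-box RecA1 + Helicase_C RecA2) is always present; families
#' differ in the state of the Lhr-specific Domain 4 (intact, deteriorated or
#' absent), the presence of an HTH_42 domain, a cysteine-rich C-terminal
#' motif, and the taxon of their genomes.
#'
#' @return data.frame with columns `name`, `domain4`, `hth42`, `cys_rich`,
#'   `taxon`.
#' @export
default_architectures <- function() {
  data.frame(
    name     = c("aLhr2", "aLhr1", "bLhr", "bLhr-HTH", "aLhr3", "Lhr-like"),
    domain4  = c("intact", "intact", "intact", "intact", "deteriorated", "absent"),
    hth42    = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    cys_rich = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    taxon    = c("Archaea", "Archaea", "Bacteria", "Bacteria", "Archaea", "Archaea"),
    stringsAsFactors = FALSE
  )
}

#' Parameters for the synthetic family generator
#'
#' Defaults describe the standard study dataset used throughout the package:
#' six families of sizes 20/12/8/4/3/2 (49 proteins), members mutated to 85%
#' identity relative to their family ancestor, ancestors mutated to 25%
#' identity relative to a common root, spread over 25 species with one strain
#' each, and a conserved neighbor gene planted next to focal genes in 60% of
#' genomes.
#'
#' @param n_families number of planted families.
#' @param family_sizes integer vector, one size per family (all >= 1).
#' @param within_identity target identity of each member to its family
#'   ancestor, in (0, 1].
#' @param between_identity target identity of each family ancestor to the
#'   shared root, in (0, 1); must be below `within_identity`.
#' @param core_length total length (residues) of the helicase core; split
#'   4:3 between the RecA1 and RecA2 segments.
#' @param architectures data.frame as [default_architectures()]; recycled or
#'   truncated to `n_families` rows.
#' @param n_species number of species; family members are assigned
#'   round-robin so no family has two members in one species when
#'   `n_species` is at least the largest family size.
#' @param strains_per_species strains per species; strain copies of a member
#'   carry identical sequences under distinct protein ids.
#' @param neighbor_conservation_prob probability that a focal gene has the
#'   planted conserved neighbor gene immediately upstream; scalar or one
#'   value per family.
#' @param window_gene_spacing gap (bp) between a planted neighbor gene and
#'   its focal gene; successive focal-gene blocks are tiled 5000 bp apart,
#'   beyond the default 4 kb context window.
#' @param seed master seed; all randomness is derived from it by stable
#'   hashing of record ids, so generation is insertion-order independent.
#' @return object of class `synth_params`.
#' @export
synth_params <- function(n_families = 6L,
                         family_sizes = c(20L, 12L, 8L, 4L, 3L, 2L),
                         within_identity = 0.85,
                         between_identity = 0.25,
                         core_length = 350L,
                         architectures = default_architectures(),
                         n_species = 25L,
                         strains_per_species = 1L,
                         neighbor_conservation_prob = 0.6,
                         window_gene_spacing = 200L,
                         seed = 7L) {
  p <- list(
    n_families = as.integer(n_families),
    family_sizes = as.integer(family_sizes),
    within_identity = within_identity,
    between_identity = between_identity,
    core_length = as.integer(core_length),
    architectures = architectures,
    n_species = as.integer(n_species),
    strains_per_species = as.integer(strains_per_species),
    neighbor_conservation_prob = neighbor_conservation_prob,
    window_gene_spacing = as.integer(window_gene_spacing),
    seed = as.integer(seed)
  )
  validate_synth_params(p)
  class(p) <- "synth_params"
  p
}

validate_synth_params <- function(p) {
  if (length(p$family_sizes) != p$n_families)
    stop_input("length(family_sizes) must equal n_families")
  if (any(p$family_sizes < 1L))
    stop_input("family_sizes must all be >= 1")
  if (!(p$within_identity > 0 && p$within_identity <= 1))
    stop_input("within_identity must be in (0, 1]")
  if (!(p$between_identity >= 0 && p$between_identity < 1))
    stop_input("between_identity must be in [0, 1)")
  if (p$within_identity <= p$between_identity)
    stop_input("within_identity must exceed between_identity")
  pr <- p$neighbor_conservation_prob
  if (any(pr < 0 | pr > 1))
    stop_input("neighbor_conservation_prob must be in [0, 1]")
  if (p$n_species < 1L || p$strains_per_species < 1L)
    stop_input("n_species and strains_per_species must be >= 1")
  invisible(p)
}

#' Mutate a sequence to a target expected identity
#'
#' Each position is substituted independently with probability
#' `1 - target_identity`; substitutions are drawn uniformly over the 19
#' alternative residues, so the expected fraction of identical positions is
#' exactly `target_identity`.
#'
#' @param seq amino-acid string over the standard 20-letter alphabet.
#' @param target_identity expected identity to `seq`, in (0, 1].
#' @param seed optional integer; if given, the result is a deterministic
#'   function of `(seq, target_identity, seed)` and the caller's RNG state
#'   is left untouched.
#' @return mutated amino-acid string of the same length.
#' @export
mutate_sequence <- function(seq, target_identity, seed = NULL) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop_input("seq must be a non-empty string")
  if (!is.numeric(target_identity) || target_identity <= 0 || target_identity > 1)
    stop_input("target_identity must be in (0, 1]")
  if (target_identity == 1) return(seq)
  run <- function() {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    idx_cur <- match(chars, AA_ALPHABET20)
    if (anyNA(idx_cur))
      stop_input("seq contains characters outside the 20-letter alphabet")
    n <- length(chars)
    mut <- stats::runif(n) < (1 - target_identity)
    k <- sum(mut)
    if (k > 0L) {
      # index into the 19 alternatives, skipping the current residue
      alt <- sample.int(19L, k, replace = TRUE)
      alt <- alt + (alt >= idx_cur[mut])
      chars[mut] <- AA_ALPHABET20[alt]
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else with_stream(as.integer(seed), run())
}

# ---- internal layout -------------------------------------------------------

# Segment layout for one architecture; lengths in residues.
family_layout <- function(arch_row, core_length) {
  recA1 <- as.integer(round(core_length * 4 / 7))
  recA2 <- core_length - recA1
  segs <- list(recA1 = recA1, linker1 = 20L, recA2 = recA2, linker2 = 10L)
  if (arch_row$domain4 != "absent") segs$domain4 <- 120L
  if (isTRUE(arch_row$hth42)) segs$hth <- 50L
  segs$tail <- 60L
  lens <- unlist(segs)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  data.frame(segment = names(segs), start = unname(starts), end = unname(ends),
             stringsAsFactors = FALSE)
}

seg_range <- function(layout, name) {
  r <- layout[layout$segment == name, , drop = FALSE]
  if (nrow(r) == 0L) NULL else c(r$start, r$end)
}

# Profile-hit rows realizing one family's architecture for one protein.
architecture_hits <- function(protein_id, protein_len, arch_row, layout) {
  rows <- list()
  add <- function(profile_id, e, bit, qs, qe, plen, cov) {
    rows[[length(rows) + 1L]] <<- data.frame(
      protein_id = protein_id, profile_id = profile_id, e_value = e,
      bit_score = bit, q_start = as.integer(qs), q_end = as.integer(qe),
      profile_len = as.integer(plen), coverage = cov,
      stringsAsFactors = FALSE)
  }
  r1 <- seg_range(layout, "recA1"); r2 <- seg_range(layout, "recA2")
  add("COG1201", 1e-60, 200, 1L, protein_len, 850L,
      round(min(1, protein_len / 850), 3))
  add("PF00270", 1e-50, 150, r1[1], r1[2], r1[2] - r1[1] + 1L, 0.95)
  add("PF00271", 1e-45, 130, r2[1], r2[2], r2[2] - r2[1] + 1L, 0.95)
  d4 <- seg_range(layout, "domain4")
  if (!is.null(d4)) {
    if (arch_row$domain4 == "intact") {
      add("PF08494", 1e-30, 90, d4[1], d4[2], 120L, 0.92)
    } else {  # deteriorated: hit covers 30% of the profile
      add("PF08494", 1e-6, 25, d4[1], d4[1] + 35L, 120L, 0.30)
    }
  }
  hth <- seg_range(layout, "hth")
  if (!is.null(hth)) add("PF06224", 1e-20, 60, hth[1], hth[2], 50L, 0.90)
  do.call(rbind, rows)
}

# Force the cysteine-rich call to match the family's architecture spec,
# regardless of what random substitution did to the C-terminal window.
realize_cys_window <- function(seq, arch_row, layout, window = 120L,
                               n_plant = 8L) {
  d4 <- seg_range(layout, "domain4")
  anchor <- if (!is.null(d4)) d4[2] else seg_range(layout, "recA2")[2]
  n <- nchar(seq)
  lo <- anchor + 1L
  hi <- min(n, anchor + window)
  if (lo > hi) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (isTRUE(arch_row$cys_rich)) {
    at <- anchor + seq.int(5L, by = 5L, length.out = n_plant)
    at <- at[at <= n]
    chars[at] <- "C"
  } else {
    win <- lo:hi
    chars[win][chars[win] == "C"] <- "S"
  }
  paste(chars, collapse = "")
}

random_aa_string <- function(n) {
  paste(sample(AA_ALPHABET20, n, replace = TRUE), collapse = "")
}

# ---- generator -------------------------------------------------------------

#' Generate a planted-family synthetic dataset
#'
#' Builds a root sequence, derives one ancestor per family by mutating the
#' root to `between_identity`, assembles each ancestor's sequence from the
#' segments its architecture calls for, then mutates members to
#' `within_identity` relative to their ancestor. Profile-hit rows realize
#' each family's architecture exactly (a "deteriorated" Domain 4 is a hit
#' covering 30% of the profile; "absent" means no hit). Genes are tiled on
#' one contig per genome on the plus strand; with the per-family neighbor
#' probability, a conserved neighbor gene (profile `TIGR0024`) is placed
#' immediately upstream of the focal gene.
#'
#' @param params a [synth_params()] object.
#' @return object of class `synth_dataset`: list with data.frames
#'   `proteins`, `profile_hits`, `features`, named vectors `truth_labels`
#'   and `truth_clusters`, and the `params` used.
#' @export
generate_family_dataset <- function(params) {
  validate_synth_params(params)
  arch <- params$architectures
  arch <- arch[rep(seq_len(nrow(arch)), length.out = params$n_families), ,
               drop = FALSE]
  nbr_prob <- rep(params$neighbor_conservation_prob,
                  length.out = params$n_families)

  # master sequence spans the largest possible layout
  full_arch <- data.frame(domain4 = "intact", hth42 = TRUE, cys_rich = FALSE)
  full_layout <- family_layout(full_arch, params$core_length)
  master_len <- max(full_layout$end)
  master <- with_stream(stream_seed(params$seed, "root"),
                        random_aa_string(master_len))

  proteins <- list(); hits <- list(); labels <- c(); clusters <- c()
  member_seqs <- list()  # family -> member -> sequence

  for (f in seq_len(params$n_families)) {
    arow <- arch[f, , drop = FALSE]
    fname <- arow$name
    layout <- family_layout(arow, params$core_length)
    anc_full <- mutate_sequence(master, params$between_identity,
                                seed = stream_seed(params$seed,
                                                   paste0("anc_", fname, "_", f)))
    # assemble from the segments this architecture uses (master coordinates)
    keep <- layout$segment
    pieces <- vapply(keep, function(s) {
      r <- seg_range(full_layout, s)
      substr(anc_full, r[1], r[2])
    }, character(1))
    anc <- paste(pieces, collapse = "")

    for (m in seq_len(params$family_sizes[f])) {
      mem_key <- sprintf("mem_%d_%d", f, m)
      s <- mutate_sequence(anc, params$within_identity,
                           seed = stream_seed(params$seed, mem_key))
      s <- realize_cys_window(s, arow, layout)
      member_seqs[[mem_key]] <- list(seq = s, layout = layout, arow = arow,
                                     family = f, fname = fname, member = m)
    }
  }

  # assign members to species round-robin; replicate across strains
  for (key in names(member_seqs)) {
    rec <- member_seqs[[key]]
    sp_idx <- ((rec$member - 1L) %% params$n_species) + 1L
    species <- sprintf("SP%02d", sp_idx)
    for (st in seq_len(params$strains_per_species)) {
      strain <- sprintf("A%02d", st)
      pid <- sprintf("%s_%s_%s_%02d", species, strain,
                     gsub("-", "", rec$fname), rec$member)
      proteins[[pid]] <- data.frame(
        protein_id = pid, species_key = species, strain_key = strain,
        taxon_group = rec$arow$taxon, sequence = rec$seq,
        length = nchar(rec$seq), family = rec$fname,
        cluster = rec$family, stringsAsFactors = FALSE)
      hits[[pid]] <- architecture_hits(pid, nchar(rec$seq), rec$arow,
                                       rec$layout)
      labels[pid] <- rec$fname
      clusters[pid] <- rec$family
    }
  }

  prot_df <- do.call(rbind, unname(proteins))
  o <- order(prot_df$protein_id)
  prot_df <- prot_df[o, , drop = FALSE]
  rownames(prot_df) <- NULL
  hit_df <- do.call(rbind, unname(hits[prot_df$protein_id]))
  rownames(hit_df) <- NULL

  features <- synth_gene_features(prot_df, nbr_prob, params)

  ds <- structure(list(
    proteins = prot_df[, c("protein_id", "species_key", "strain_key",
                           "taxon_group", "sequence", "length")],
    profile_hits = hit_df,
    features = features,
    truth_labels = labels[prot_df$protein_id],
    truth_clusters = clusters[prot_df$protein_id],
    params = params
  ), class = "synth_dataset")
  validate_synth_dataset(ds)
  ds
}

# Tile genes on one + strand contig per genome; optionally place the
# conserved neighbor immediately upstream of each focal gene.
synth_gene_features <- function(prot_df, nbr_prob, params) {
  fam_index <- params$architectures$name
  fam_of <- function(fname) match(fname, fam_index)
  rows <- list()
  genomes <- unique(prot_df[, c("species_key", "strain_key")])
  genomes <- genomes[order(genomes$species_key, genomes$strain_key), ,
                     drop = FALSE]
  spacing <- params$window_gene_spacing
  # successive focal-gene blocks are separated by more than the 4 kb
  # context window, so a planted neighbor is only in its own focal gene's
  # neighborhood
  block_gap <- 5000L
  for (g in seq_len(nrow(genomes))) {
    gid <- paste(genomes$species_key[g], genomes$strain_key[g], sep = "_")
    contig <- paste0(gid, "_c1")
    sub <- prot_df[prot_df$species_key == genomes$species_key[g] &
                   prot_df$strain_key == genomes$strain_key[g], , drop = FALSE]
    cursor <- 1L
    for (i in seq_len(nrow(sub))) {
      pid <- sub$protein_id[i]
      fidx <- fam_of(sub$family[i])
      p <- nbr_prob[((fidx - 1L) %% length(nbr_prob)) + 1L]
      draw <- with_stream(stream_seed(params$seed, paste0("nbr_", pid)), {
        list(has = stats::runif(1) < p,
             strand = sample(c("+", "-"), 1L))
      })
      if (draw$has) {
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = gid, contig_id = contig,
          feature_id = paste0(pid, "_nbr"),
          start = cursor, end = cursor + 899L, strand = draw$strand,
          product_id = paste0(pid, "_nbr"), product_profile = "TIGR0024",
          stringsAsFactors = FALSE)
        cursor <- cursor + 900L + spacing
      }
      glen <- 3L * sub$length[i] + 3L
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = gid, contig_id = contig, feature_id = pid,
        start = cursor, end = cursor + glen - 1L, strand = "+",
        product_id = pid, product_profile = "COG1201",
        stringsAsFactors = FALSE)
      cursor <- cursor + glen + block_gap
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(genome_id = character(), contig_id = character(),
                      feature_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      product_id = character(), product_profile = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

validate_synth_dataset <- function(ds) {
  stopifnot(all(ds$proteins$protein_id %in% names(ds$truth_labels)))
  if (nrow(ds$profile_hits) > 0L) {
    len <- setNames(ds$proteins$length, ds$proteins$protein_id)
    h <- ds$profile_hits
    ok <- h$q_start >= 1L & h$q_end <= len[h$protein_id] &
      h$q_start <= h$q_end
    if (!all(ok)) stop_input("profile hit coordinates outside protein bounds")
  }
  invisible(ds)
}

# ---- fixture bundle I/O ----------------------------------------------------

#' Write a synthetic dataset to a fixture directory
#'
#' Writes `proteins.fasta`, `profile_hits.tsv` (domtblout-like dialect),
#' `features.gff3` and `truth.tsv` (truth labels plus proteome metadata).
#' Output is byte-identical across runs for identical datasets.
#'
#' @param dataset a `synth_dataset`.
#' @param dir destination directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture_bundle <- function(dataset, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop_input("cannot create directory: ", dir)
  }
  paths <- c(
    fasta = file.path(dir, "proteins.fasta"),
    hits = file.path(dir, "profile_hits.tsv"),
    gff = file.path(dir, "features.gff3"),
    truth = file.path(dir, "truth.tsv")
  )
  aa <- Biostrings::AAStringSet(setNames(dataset$proteins$sequence,
                                         dataset$proteins$protein_id))
  Biostrings::writeXStringSet(aa, paths[["fasta"]])
  write_profile_hits_tsv(dataset$profile_hits, paths[["hits"]])
  write_gff3(dataset$features, paths[["gff"]])
  truth <- data.frame(
    protein_id = dataset$proteins$protein_id,
    family_label = unname(dataset$truth_labels[dataset$proteins$protein_id]),
    cluster_id = unname(dataset$truth_clusters[dataset$proteins$protein_id]),
    species_key = dataset$proteins$species_key,
    strain_key = dataset$proteins$strain_key,
    taxon_group = dataset$proteins$taxon_group,
    stringsAsFactors = FALSE)
  write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Read a fixture bundle written by [write_fixture_bundle()]
#' @param dir directory containing the four fixture files.
#' @return a `synth_dataset` (with `params = NULL`).
#' @export
read_fixture_bundle <- function(dir) {
  aa <- Biostrings::readAAStringSet(file.path(dir, "proteins.fasta"))
  truth <- read.delim(file.path(dir, "truth.tsv"), sep = "\t",
                      stringsAsFactors = FALSE)
  ids <- sub("\\s.*$", "", names(aa))
  prot <- data.frame(
    protein_id = ids,
    species_key = truth$species_key[match(ids, truth$protein_id)],
    strain_key = truth$strain_key[match(ids, truth$protein_id)],
    taxon_group = truth$taxon_group[match(ids, truth$protein_id)],
    sequence = as.character(aa),
    length = Biostrings::width(aa),
    stringsAsFactors = FALSE)
  rownames(prot) <- NULL
  ds <- structure(list(
    proteins = prot,
    profile_hits = read_profile_hits_tsv(file.path(dir, "profile_hits.tsv")),
    features = read_gff3(file.path(dir, "features.gff3")),
    truth_labels = setNames(truth$family_label, truth$protein_id),
    truth_clusters = setNames(truth$cluster_id, truth$protein_id),
    params = NULL
  ), class = "synth_dataset")
  ds
}
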