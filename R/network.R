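# Reaction-network representation: species table + mass-action reaction list.
# Canonical units are molecules/cell, minutes, and (for second-order
# constants) 1/(min * molecule).

AVOGADRO <- 6.02214076e23

VALID_TAGS <- c("surface", "internalized", "degraded", "output", "stimulus")

#' Construct a species specification table
#'
#' Builds the species table of a [reaction_network()]. Tags mark the role a
#' species plays in the analysis: `stimulus` (the input ligand), `output`
#' (the network readouts, e.g. doubly phosphorylated ERK), `surface` /
#' `internalized` (the plasma-membrane and endosomal routes of the cascade)
#' and `degraded` (bookkeeping degradation products).
#'
#' @param id character vector of short unique species identifiers.
#' @param initial_amount numeric vector of initial amounts (molecules/cell
#'   in the canonical unit; see `amount_unit`).
#' @param name display names; defaults to `id`.
#' @param tags list of character vectors (one per species), each a subset of
#'   `surface, internalized, degraded, output, stimulus`.
#' @param mol_weight molecular weights in g/mol, needed only to convert
#'   mass concentrations (ng/mL); `NA` otherwise.
#' @param amount_unit one of `"molecules"`, `"nM"`, `"ng_per_mL"` per
#'   species; non-canonical units are converted by [rescale_units()].
#' @return a `data.frame` with one row per species.
#' @export
species_table <- function(id, initial_amount, name = id,
                          tags = vector("list", length(id)),
                          mol_weight = rep(NA_real_, length(id)),
                          amount_unit = rep("molecules", length(id))) {
  stopifnot(length(initial_amount) == length(id))
  tags <- lapply(tags, function(tg) as.character(tg %||% character()))
  df <- data.frame(id = as.character(id), name = as.character(name),
                   initial_amount = as.numeric(initial_amount),
                   mol_weight = as.numeric(mol_weight),
                   amount_unit = as.character(amount_unit),
                   stringsAsFactors = FALSE)
  df$tags <- tags
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a mass-action reaction
#'
#' @param reactants,products character vectors of species ids; a
#'   stoichiometric coefficient may be given as a prefix, e.g. `"2 EGFR"`.
#' @param kf forward rate constant (canonically 1/min for first order,
#'   1/(min*molecule) for second order).
#' @param kr reverse rate constant, or `NA` for an irreversible reaction.
#' @param time_unit `"per_min"` (canonical) or `"per_sec"`.
#' @param conc_unit basis of second-order constants: `"per_molecule"`
#'   (canonical) or `"per_nM"`.
#' @return a list of class `"reaction_spec"`.
#' @export
reaction <- function(reactants, products, kf, kr = NA_real_,
                     time_unit = "per_min", conc_unit = "per_molecule") {
  structure(list(reactants = parse_side(reactants),
                 products = parse_side(products),
                 kf = as.numeric(kf), kr = as.numeric(kr),
                 time_unit = time_unit, conc_unit = conc_unit),
            class = "reaction_spec")
}

# "2 X" -> stoich 2 of species X; plain id -> stoich 1
parse_side <- function(side) {
  side <- as.character(side)
  m <- regmatches(side, regexec("^\\s*([0-9]+)\\s+(\\S+)\\s*$", side))
  stoich <- vapply(m, function(x) if (length(x)) as.numeric(x[2]) else 1,
                   numeric(1))
  id <- mapply(function(x, s) if (length(x)) x[3] else trimws(s),
               m, side, USE.NAMES = FALSE)
  data.frame(id = id, stoich = stoich, stringsAsFactors = FALSE)
}

format_side <- function(df) {
  vapply(seq_len(nrow(df)), function(i) {
    if (df$stoich[i] == 1) df$id[i] else paste(df$stoich[i], df$id[i])
  }, character(1))
}

#' Construct a reaction network
#'
#' The central container of the package: a set of species with initial
#' amounts and a list of mass-action reactions (order at most two), plus
#' the cell volume used for unit conversions.
#'
#' @param species a [species_table()].
#' @param reactions a list of [reaction()] objects.
#' @param cell_volume cell volume in litres (default 1e-12 L).
#' @param tracked optional character vector of species ids to include in
#'   profile analyses; defaults (at use time) to every species not tagged
#'   `stimulus` or `degraded`-sink bookkeeping (see [tracked_ids()]).
#' @return an object of class `"reaction_network"`.
#' @export
reaction_network <- function(species, reactions, cell_volume = 1e-12,
                             tracked = NULL) {
  net <- structure(list(species = species, reactions = reactions,
                        cell_volume = cell_volume, tracked = tracked,
                        knocked = character()),
                   class = "reaction_network")
  validate_network(net)
  net
}

#' Validate a reaction network
#'
#' Checks referential integrity, non-negative amounts and rate constants,
#' reaction order at most two, unique ids, positive cell volume, and at
#' most one stimulus species. With `strict = TRUE` (used by pipeline
#' stages) additionally requires exactly one stimulus and at least one
#' output species.
#'
#' @param net a `reaction_network`.
#' @param strict require stimulus/output designations.
#' @return `net`, invisibly; stops on violation.
#' @export
validate_network <- function(net, strict = FALSE) {
  sp <- net$species
  if (anyDuplicated(sp$id))
    stop("structural error: duplicate species ids: ",
         paste(unique(sp$id[duplicated(sp$id)]), collapse = ", "))
  if (any(sp$initial_amount < 0))
    stop("structural error: negative initial amount for ",
         paste(sp$id[sp$initial_amount < 0], collapse = ", "))
  bad_tags <- setdiff(unlist(sp$tags), VALID_TAGS)
  if (length(bad_tags))
    stop("structural error: unknown tags: ", paste(bad_tags, collapse = ", "))
  if (!is.numeric(net$cell_volume) || net$cell_volume <= 0)
    stop("structural error: cell_volume must be > 0")
  n_stim <- length(species_with_tag(net, "stimulus"))
  if (n_stim > 1) stop("structural error: more than one stimulus species")
  for (i in seq_along(net$reactions)) {
    rx <- net$reactions[[i]]
    ids <- c(rx$reactants$id, rx$products$id)
    missing <- setdiff(ids, sp$id)
    if (length(missing))
      stop("structural error: reaction ", i, " references undeclared species ",
           paste(missing, collapse = ", "))
    if (sum(rx$reactants$stoich) > 2)
      stop("structural error: reaction ", i, " has order > 2")
    if (!is.na(rx$kf) && rx$kf < 0) stop("structural error: negative kf")
    if (!is.na(rx$kr) && rx$kr < 0) stop("structural error: negative kr")
  }
  if (!is.null(net$tracked)) {
    missing <- setdiff(net$tracked, sp$id)
    if (length(missing))
      stop("structural error: tracked list references undeclared species ",
           paste(missing, collapse = ", "))
  }
  if (strict) {
    if (n_stim != 1)
      stop("structural error: exactly one stimulus species required")
    if (length(species_with_tag(net, "output")) < 1)
      stop("structural error: at least one output species required")
  }
  invisible(net)
}

species_with_tag <- function(net, tag) {
  has <- vapply(net$species$tags, function(tg) tag %in% tg, logical(1))
  net$species$id[has]
}

#' Species ids tracked in profile analyses
#'
#' The tracked set defaults to every species except the stimulus ligand;
#' a network may carry an explicit `tracked` list (configured in the model
#' file) that overrides the default.
#'
#' @param net a `reaction_network`.
#' @return character vector of species ids.
#' @export
tracked_ids <- function(net) {
  if (!is.null(net$tracked)) return(net$tracked)
  setdiff(net$species$id, species_with_tag(net, "stimulus"))
}

#' Output species of a network
#' @param net a `reaction_network`.
#' @return character vector of ids tagged `output`.
#' @export
output_ids <- function(net) species_with_tag(net, "output")

#' Stimulus species of a network
#' @param net a `reaction_network`.
#' @return the id tagged `stimulus` (length 0 if none).
#' @export
stimulus_id <- function(net) species_with_tag(net, "stimulus")

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction_network:", nrow(x$species), "species,",
      length(x$reactions), "reactions\n")
  cat("  cell volume:", format(x$cell_volume), "L\n")
  st <- stimulus_id(x); ou <- output_ids(x)
  if (length(st)) cat("  stimulus:", st, "\n")
  if (length(ou)) cat("  outputs:", paste(ou, collapse = ", "), "\n")
  if (length(x$knocked))
    cat("  knocked out:", paste(x$knocked, collapse = ", "), "\n")
  invisible(x)
}

#' Convert a network to canonical units
#'
#' Rescales every species amount to molecules/cell and every rate constant
#' to a per-minute basis (second-order constants to 1/(min*molecule)),
#' using the given cell volume. Amounts already in molecules/cell and
#' constants already per-minute are left untouched, so the operation is
#' idempotent. Conversions: 1 nM in volume V litres equals
#' `1e-9 * V * N_A` molecules; a mass concentration in ng/mL requires the
#' species' molecular weight (g/mol) from the model file.
#'
#' @param net a `reaction_network`.
#' @param cell_volume cell volume in litres; defaults to the network's own.
#' @return a new `reaction_network` in canonical units; topology and
#'   stoichiometry are untouched.
#' @export
rescale_units <- function(net, cell_volume = net$cell_volume) {
  stopifnot(cell_volume > 0)
  molecules_per_nM <- 1e-9 * cell_volume * AVOGADRO
  sp <- net$species
  for (i in seq_len(nrow(sp))) {
    u <- sp$amount_unit[i]
    if (u == "molecules") next
    if (u == "nM") {
      sp$initial_amount[i] <- sp$initial_amount[i] * molecules_per_nM
    } else if (u == "ng_per_mL") {
      if (is.na(sp$mol_weight[i]))
        stop("unit error: species ", sp$id[i],
             " has a mass concentration but no molecular weight")
      # ng/mL = 1e-6 g/L; molecules = (g/L / MW) * N_A * V
      sp$initial_amount[i] <-
        sp$initial_amount[i] * 1e-6 / sp$mol_weight[i] * AVOGADRO * cell_volume
    } else stop("unit error: unknown amount unit '", u, "'")
    sp$amount_unit[i] <- "molecules"
  }
  rxs <- lapply(net$reactions, function(rx) {
    fac_t <- if (rx$time_unit == "per_sec") 60 else 1
    order2 <- sum(rx$reactants$stoich) == 2
    fac_cf <- if (order2 && rx$conc_unit == "per_nM") 1 / molecules_per_nM else 1
    rx$kf <- rx$kf * fac_t * fac_cf
    if (!is.na(rx$kr)) {
      rev_order2 <- sum(rx$products$stoich) == 2
      fac_cr <- if (rev_order2 && rx$conc_unit == "per_nM") 1 / molecules_per_nM else 1
      rx$kr <- rx$kr * fac_t * fac_cr
    }
    rx$time_unit <- "per_min"; rx$conc_unit <- "per_molecule"
    rx
  })
  out <- net
  out$species <- sp; out$reactions <- rxs; out$cell_volume <- cell_volume
  out
}

#' Knock a species out of a network
#'
#' Implements in-silico protein removal: the species' initial amount is set
#' to zero and its time derivative is pinned at zero for all time, so its
#' concentration stays identically zero. Reactions are not deleted;
#' reactions consuming the species simply see zero substrate. The input
#' network is not modified.
#'
#' @param net a `reaction_network`.
#' @param species_id id of the species to remove.
#' @return a new `reaction_network` with the knockout recorded.
#' @export
apply_knockout <- function(net, species_id) {
  if (!species_id %in% net$species$id)
    stop("lookup error: unknown species '", species_id, "'")
  out <- net
  out$species$initial_amount[out$species$id == species_id] <- 0
  out$knocked <- union(out$knocked, species_id)
  out
}

#' Perturb every rate constant with multiplicative Gaussian noise
#'
#' Each rate constant k is replaced by `k * (1 + eps)` with
#' `eps ~ Normal(0, (noise_pct/100)^2)`, drawn independently per constant
#' and clipped below at zero to keep rates physical. Reproducible given
#' `seed`.
#'
#' @param net a `reaction_network`.
#' @param noise_pct noise standard deviation as percent of each constant.
#' @param seed integer seed.
#' @return a new `reaction_network` with perturbed constants.
#' @export
perturb_rates <- function(net, noise_pct, seed) {
  if (noise_pct < 0) stop("domain error: noise_pct must be >= 0")
  out <- net
  if (noise_pct == 0) return(out)
  rng <- local_rng(seed)
  sd <- noise_pct / 100
  out$reactions <- lapply(net$reactions, function(rx) {
    rx$kf <- max(0, rx$kf * (1 + rng$rnorm(1, sd = sd)))
    if (!is.na(rx$kr)) rx$kr <- max(0, rx$kr * (1 + rng$rnorm(1, sd = sd)))
    rx
  })
  out
}

# Seeded RNG sandbox that restores the global .Random.seed on exit,
# so package functions never disturb the caller's RNG stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  state <- get(".Random.seed", globalenv())
  restore <- function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
  use <- function(f, ...) {
    assign(".Random.seed", state, envir = globalenv())
    on.exit({state <<- get(".Random.seed", globalenv()); restore()})
    f(...)
  }
  list(rnorm = function(...) use(stats::rnorm, ...),
       runif = function(...) use(stats::runif, ...),
       sample = function(...) use(base::sample, ...),
       rlnorm = function(...) use(stats::rlnorm, ...))
}
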