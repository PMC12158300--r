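# Construction of the brain-state observation matrix from an aligned
# run: the full 7-channel Spearman network (FCNet), its MC / LOC /
# MC-LOC subnetworks, region pooling, and the mesoscale network (MNet).

#' Region scheme
#'
#' Names the channel sets used for subnetwork extraction and region
#' pooling. Note the deliberate asymmetry: the LOC *subnetwork* carries
#' four channels (P7, Pz, PO3, Oz) while LOC *pooling* for the mesoscale
#' network uses only P7, Pz and Oz.
#'
#' @param mc_channels motor-cortex channels (default C3, Cz, C4).
#' @param loc_channels occipital subnetwork channels (default P7, Pz,
#'   PO3, Oz).
#' @param lmc,rmc,loc_pool pooling sets for the mesoscale regions.
#' @return a `region_scheme` list.
#' @export
region_scheme <- function(mc_channels = c("C3", "Cz", "C4"),
                          loc_channels = c("P7", "Pz", "PO3", "Oz"),
                          lmc = c("C3", "Cz"),
                          rmc = c("C4", "Cz"),
                          loc_pool = c("P7", "Pz", "Oz")) {
  all_named <- unique(c(mc_channels, loc_channels, lmc, rmc, loc_pool))
  bad <- setdiff(all_named, CANONICAL_CHANNELS)
  if (length(bad) > 0)
    stopf("region_scheme names unknown channel(s): %s", paste(bad, collapse = ", "))
  if (length(intersect(mc_channels, loc_channels)) > 0)
    stopf("MC and LOC subnetwork channels must be disjoint")
  structure(list(mc_channels = mc_channels, loc_channels = loc_channels,
                 lmc = lmc, rmc = rmc, loc_pool = loc_pool),
            class = "region_scheme")
}

spearman_matrix <- function(m, what) {
  const <- apply(m, 1, function(r) diff(range(r)) == 0)
  if (any(const))
    stopf("%s: constant channel(s): %s", what,
          paste(rownames(m)[const], collapse = ", "))
  r <- stats::cor(t(m), method = "spearman")
  dimnames(r) <- list(rownames(m), rownames(m))
  r
}

#' Spearman fully connected network (FCNet)
#'
#' Entry (i, j) is the Spearman rank correlation (average ranks for ties)
#' between channels i and j over the run.
#'
#' @param run an [aligned_run()] with at least 3 samples.
#' @return symmetric 7x7 matrix with unit diagonal, canonical dimnames.
#' @export
spearman_network <- function(run) {
  if (ncol(run$data) < 3) stopf("spearman_network needs >= 3 samples")
  spearman_matrix(run$data, "spearman_network")
}

#' Extract subnetworks from an FCNet
#'
#' @param net 7x7 FCNet with canonical dimnames.
#' @param scheme a [region_scheme()].
#' @return list with `mc` (3x3), `loc` (4x4) and `mc_loc` (3x4) blocks.
#' @export
extract_subnets <- function(net, scheme = region_scheme()) {
  missing <- setdiff(c(scheme$mc_channels, scheme$loc_channels), rownames(net))
  if (length(missing) > 0)
    stopf("FCNet is missing channel(s): %s", paste(missing, collapse = ", "))
  list(mc = net[scheme$mc_channels, scheme$mc_channels],
       loc = net[scheme$loc_channels, scheme$loc_channels],
       mc_loc = net[scheme$mc_channels, scheme$loc_channels])
}

#' Pool channels into mesoscale region signals
#'
#' Sample-wise arithmetic mean over each region's channels: LMC from
#' (C3, Cz), RMC from (C4, Cz), LOC from (P7, Pz, Oz).
#'
#' @param run an [aligned_run()].
#' @param scheme a [region_scheme()].
#' @return 3 x samples matrix with rows LMC, RMC, LOC.
#' @export
pool_regions <- function(run, scheme = region_scheme()) {
  d <- run$data
  pooled <- rbind(LMC = colMeans(d[scheme$lmc, , drop = FALSE]),
                  RMC = colMeans(d[scheme$rmc, , drop = FALSE]),
                  LOC = colMeans(d[scheme$loc_pool, , drop = FALSE]))
  pooled
}

#' Mesoscale network (MNet)
#'
#' Spearman correlations between the pooled region series.
#'
#' @param pooled 3 x samples matrix from [pool_regions()].
#' @return symmetric 3x3 matrix (LMC, RMC, LOC).
#' @export
mesoscale_network <- function(pooled) {
  if (ncol(pooled) < 3) stopf("mesoscale_network needs >= 3 samples")
  spearman_matrix(pooled, "mesoscale_network")
}

#' Assemble the brain-state observation matrix of one run
#'
#' Composes the FCNet subnetwork extraction with region pooling and the
#' mesoscale network into the four-block observation.
#'
#' @param run an [aligned_run()].
#' @param scheme a [region_scheme()].
#' @return an [observation_matrix()].
#' @export
assemble_observation <- function(run, scheme = region_scheme()) {
  net <- spearman_network(run)
  sub <- extract_subnets(net, scheme)
  mnet <- mesoscale_network(pool_regions(run, scheme))
  observation_matrix(sub$mc, sub$loc, sub$mc_loc, mnet)
}

#' Build a session chain of observations from runs
#'
#' @param runs list of [aligned_run()]s of one condition, in trial order.
#' @param condition chain label.
#' @param session_id identifier.
#' @param scheme a [region_scheme()].
#' @return a `session_chain` list (`states`, `condition`, `session_id`).
#' @export
chain_from_runs <- function(runs, condition, session_id = "S001",
                            scheme = region_scheme()) {
  structure(list(condition = condition,
                 session_id = session_id,
                 states = lapply(runs, assemble_observation, scheme = scheme)),
            class = "session_chain")
}
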