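# Network representation, native-format round trips, unit rescaling,
# knockout and rate perturbation.

test_that("minimal native model round-trips and validates", {
  net <- decay_network()
  expect_equal(nrow(net$species), 2)
  expect_length(net$reactions, 1)

  path <- withr::local_tempfile(fileext = ".yaml")
  write_network(net, path)
  back <- load_network(path, "native")
  expect_equal(back$species$id, net$species$id)
  expect_equal(back$species$initial_amount, net$species$initial_amount)
  expect_equal(back$cell_volume, net$cell_volume)
  expect_equal(back$reactions[[1]]$kf, net$reactions[[1]]$kf)
})

test_that("toy-cascade fixture round-trips field by field", {
  net <- make_toy_cascade(seed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_network(net, path)
  back <- load_network(path, "native")
  expect_equal(back$species$id, net$species$id)
  expect_equal(back$species$initial_amount, net$species$initial_amount)
  expect_equal(back$species$tags, net$species$tags)
  expect_equal(length(back$reactions), length(net$reactions))
  for (i in seq_along(net$reactions)) {
    expect_equal(back$reactions[[i]]$reactants, net$reactions[[i]]$reactants)
    expect_equal(back$reactions[[i]]$products, net$reactions[[i]]$products)
    expect_equal(back$reactions[[i]]$kf, net$reactions[[i]]$kf)
    expect_equal(back$reactions[[i]]$kr, net$reactions[[i]]$kr)
  }
})

test_that("undeclared species references raise structural errors", {
  expect_error(
    reaction_network(species_table("A", 1),
                     list(reaction("A", "X", kf = 1))),
    "structural error.*X")
  expect_error(
    reaction_network(species_table(c("A", "A"), c(1, 1)), list()),
    "duplicate")
  expect_error(
    reaction_network(species_table("A", -1), list()),
    "negative initial amount")
})

test_that("unit rescaling follows dimensional analysis", {
  # first order: /sec -> x60 /min
  net <- reaction_network(
    species_table(c("A", "B"), c(10, 0)),
    list(reaction("A", "B", kf = 1, time_unit = "per_sec")))
  expect_equal(rescale_units(net)$reactions[[1]]$kf, 60)

  # second order: 1/(nM s) at V = 1e-12 L -> 60 / (1e-9 * V * N_A)
  net2 <- reaction_network(
    species_table(c("A", "B", "C"), c(10, 10, 0)),
    list(reaction(c("A", "B"), "C", kf = 1,
                  time_unit = "per_sec", conc_unit = "per_nM")),
    cell_volume = 1e-12)
  molecules_per_nM <- 1e-9 * 1e-12 * 6.02214076e23  # ~602.2
  expect_equal(molecules_per_nM, 602.214076)
  expect_equal(rescale_units(net2)$reactions[[1]]$kf, 60 / molecules_per_nM)
  expect_equal(60 / molecules_per_nM, 0.0996, tolerance = 1e-3)

  # canonical networks are a fixed point; topology untouched
  net3 <- make_toy_cascade(seed = 1)
  r <- rescale_units(net3)
  expect_equal(r$species$initial_amount, net3$species$initial_amount)
  expect_equal(length(r$reactions), length(net3$reactions))
  expect_identical(rescale_units(r), r)

  # ng/mL requires a molecular weight
  net4 <- reaction_network(
    species_table("A", 5, amount_unit = "ng_per_mL"), list())
  expect_error(rescale_units(net4), "unit error")
  net5 <- reaction_network(
    species_table("A", 5, amount_unit = "ng_per_mL", mol_weight = 6045),
    list())
  # 5 ng/mL = 5e-6 g/L; molecules = 5e-6/6045 * N_A * 1e-12
  expect_equal(rescale_units(net5)$species$initial_amount,
               5e-6 / 6045 * 6.02214076e23 * 1e-12)
})

test_that("knockout pins the species and is idempotent and non-mutating", {
  net <- small_cascade()
  ko <- apply_knockout(net, "P1")
  expect_equal(net$knocked, character())  # input untouched
  expect_equal(nrow(ko$species), nrow(net$species))
  expect_length(ko$reactions, length(net$reactions))
  expect_identical(apply_knockout(ko, "P1"), ko)
  expect_error(apply_knockout(net, "nope"), "lookup error")

  # knocked species stays identically zero through a simulation
  tr <- integrate_network(ko, 250)
  expect_true(all(tr$amounts["P1", ] == 0))

  # stimulus knockout: all activation identically zero
  ks <- apply_knockout(net, "S")
  tr0 <- integrate_network(ks, 250)
  for (id in c("RS", "X1a", "X2a", "X3a"))
    expect_true(all(tr0$amounts[id, ] == 0))
})

test_that("knockout of a species outside the output's ancestry is inert", {
  # side branch: X2a also converts a dead-end substrate D -> Da
  net <- small_cascade()
  net$species <- rbind(net$species,
                       species_table(c("D", "Da"), c(100, 0)))
  net$reactions <- c(net$reactions,
                     list(reaction(c("X2a", "D"), c("X2a", "Da"), kf = 1e-4)))
  validate_network(net)
  base <- integrate_network(net, 250)
  kod <- integrate_network(apply_knockout(net, "D"), 250)
  expect_equal(kod$amounts["X3a", ], base$amounts["X3a", ], tolerance = 1e-8)
})

test_that("rate perturbation is seeded, zero-safe, and well calibrated", {
  net <- small_cascade()
  expect_identical(perturb_rates(net, 0, seed = 1)$reactions, net$reactions)
  p1 <- perturb_rates(net, 10, seed = 42)
  p2 <- perturb_rates(net, 10, seed = 42)
  expect_identical(p1$reactions, p2$reactions)
  expect_false(identical(p1$reactions, perturb_rates(net, 10, 43)$reactions))
  expect_error(perturb_rates(net, -1, seed = 1), "domain error")
  expect_equal(nrow(p1$species), nrow(net$species))

  # law of large numbers on 1e4 constants at 10% noise
  big <- reaction_network(
    species_table(c("A", "B"), c(1, 0)),
    replicate(10000, reaction("A", "B", kf = 1), simplify = FALSE))
  pb <- perturb_rates(big, 10, seed = 7)
  eps <- vapply(pb$reactions, `[[`, numeric(1), "kf") - 1
  expect_lt(abs(mean(eps)), 0.005)
  expect_lt(abs(sd(eps) - 0.1), 0.005 * 10)  # within 10% +/- 0.5% nominal
})

test_that("SBML mass-action import reads species, amounts and rates", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
 <model id="toy">
  <listOfSpecies>
   <species id="A" initialAmount="100"/>
   <species id="B" initialAmount="0"/>
   <species id="C" initialAmount="5"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="r1" reversible="false">
    <listOfReactants><speciesReference species="A"/></listOfReactants>
    <listOfProducts><speciesReference species="B"/></listOfProducts>
    <kineticLaw>
     <math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><times/><ci>k1</ci><ci>A</ci></apply>
     </math>
     <listOfParameters><parameter id="k1" value="0.25"/></listOfParameters>
    </kineticLaw>
   </reaction>
   <reaction id="r2" reversible="true">
    <listOfReactants>
     <speciesReference species="B"/><speciesReference species="C"/>
    </listOfReactants>
    <listOfProducts><speciesReference species="A"/></listOfProducts>
    <kineticLaw>
     <math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><minus/>
       <apply><times/><ci>kf</ci><ci>B</ci><ci>C</ci></apply>
       <apply><times/><ci>kr</ci><ci>A</ci></apply>
      </apply>
     </math>
     <listOfParameters>
      <parameter id="kf" value="0.01"/><parameter id="kr" value="2"/>
     </listOfParameters>
    </kineticLaw>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, path)
  net <- load_network(path, "sbml")
  expect_equal(net$species$id, c("A", "B", "C"))
  expect_equal(net$species$initial_amount, c(100, 0, 5))
  expect_equal(net$reactions[[1]]$kf, 0.25)
  expect_equal(net$reactions[[2]]$kf, 0.01)
  expect_equal(net$reactions[[2]]$kr, 2)
})

test_that("non-mass-action SBML kinetic laws are rejected", {
  sbml <- '<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
 <model><listOfSpecies><species id="A" initialAmount="1"/>
  <species id="B" initialAmount="0"/></listOfSpecies>
  <listOfReactions><reaction id="r1">
   <listOfReactants><speciesReference species="A"/></listOfReactants>
   <listOfProducts><speciesReference species="B"/></listOfProducts>
   <kineticLaw>
    <math xmlns="http://www.w3.org/1998/Math/MathML">
     <apply><divide/>
      <apply><times/><ci>Vmax</ci><ci>A</ci></apply>
      <apply><plus/><ci>Km</ci><ci>A</ci></apply>
     </apply>
    </math>
    <listOfParameters><parameter id="Vmax" value="1"/>
     <parameter id="Km" value="10"/></listOfParameters>
   </kineticLaw>
  </reaction></listOfReactions></model></sbml>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, path)
  expect_error(load_network(path, "sbml"), "format error")
})

test_that("CellML reaction markup imports; pure-ODE documents are rejected", {
  cellml <- '<?xml version="1.0"?>
<model xmlns="http://www.cellml.org/cellml/1.0#" name="toy">
 <component name="main">
  <variable name="A" initial_value="100"/>
  <variable name="B" initial_value="0"/>
  <variable name="k1" initial_value="0.25"/>
  <reaction>
   <variable_ref variable="A"><role role="reactant"/></variable_ref>
   <variable_ref variable="B"><role role="product"/></variable_ref>
   <variable_ref variable="k1"><role role="rate"/></variable_ref>
  </reaction>
 </component>
</model>'
  path <- withr::local_tempfile(fileext = ".cellml")
  writeLines(cellml, path)
  net <- load_network(path, "cellml")
  expect_equal(sort(net$species$id), c("A", "B"))
  expect_equal(net$reactions[[1]]$kf, 0.25)

  no_rx <- '<?xml version="1.0"?>
<model xmlns="http://www.cellml.org/cellml/1.0#" name="ode">
 <component name="main"><variable name="A" initial_value="1"/></component>
</model>'
  path2 <- withr::local_tempfile(fileext = ".cellml")
  writeLines(no_rx, path2)
  expect_error(load_network(path2, "cellml"), "format error")
})
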