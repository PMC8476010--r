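# Small fixture models built in code.

# S1 -> 0 with rate k: dX/dt = -k X
decay_rbm <- function(k = 1, x0 = 1) {
  rbm(A = matrix(1, 1, 1), B = matrix(0, 1, 1), K = k, X0 = x0)
}

# A <-> B, k1 = k2 = 1: symmetric equilibrium [0.5, 0.5]
reversible_rbm <- function(k1 = 1, k2 = 1, x0 = c(1, 0)) {
  rbm(A = rbind(c(1, 0), c(0, 1)), B = rbind(c(0, 1), c(1, 0)),
      K = c(k1, k2), X0 = x0)
}

# Robertson problem as a mass-action network:
#   A -> B (0.04); B + C -> A + C (1e4); 2B -> B + C (3e7)
robertson_rbm <- function() {
  A <- rbind(c(1, 0, 0), c(0, 1, 1), c(0, 2, 0))
  B <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 1))
  rbm(A, B, K = c(0.04, 1e4, 3e7), X0 = c(1, 0, 0),
      species = c("A", "B", "C"))
}

# Closed system with two independent linear invariants (A+C, B+C):
#   A + B -> C ; C -> A + B
closed_rbm <- function(k1 = 2, k2 = 1, x0 = c(0.6, 0.3, 0.1)) {
  rbm(A = rbind(c(1, 1, 0), c(0, 0, 1)), B = rbind(c(0, 0, 1), c(1, 1, 0)),
      K = c(k1, k2), X0 = x0)
}

# Brusselator as a mass-action network; Hopf bifurcation at b = 1 + a^2.
#   0 -> X (a); X -> Y (b); 2X + Y -> 3X (1); X -> 0 (1)
brusselator_rbm <- function(a = 1, b = 3) {
  A <- rbind(c(0, 0), c(1, 0), c(2, 1), c(1, 0))
  B <- rbind(c(1, 0), c(0, 1), c(3, 0), c(0, 0))
  rbm(A, B, K = c(a, b, 1, 1), X0 = c(1, 1), species = c("X", "Y"))
}

# Brute-force mass-action rhs: per-reaction accumulation loop, the
# independent oracle for the vectorized implementation.
rhs_oracle <- function(m, x, k = m$K) {
  dx <- numeric(ncol(m$A))
  for (i in seq_len(nrow(m$A))) {
    flux <- k[i] * prod(x^m$A[i, ])
    dx <- dx + (m$B[i, ] - m$A[i, ]) * flux
  }
  dx
}

# Central finite-difference Jacobian oracle.
jac_oracle <- function(m, x, step = 1e-6) {
  N <- length(x)
  J <- matrix(0, N, N)
  for (q in seq_len(N)) {
    h <- step * max(1, abs(x[q]))
    xp <- x; xp[q] <- xp[q] + h
    xm <- x; xm[q] <- xm[q] - h
    J[, q] <- (mass_action_rhs(m, xp) - mass_action_rhs(m, xm)) / (2 * h)
  }
  J
}

# Build a bare trajectory object for summary-function unit tests.
fake_trajectory <- function(times, states, status = "success") {
  states <- as.matrix(states)
  rbmsim:::new_trajectory(times, states, "DOPRI5", status,
                          10L, 10L, 0L)
}

# Minimal SBML documents used by the import tests.
sbml_mass_action <- function(path) {
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
 <model id="toy">
  <listOfCompartments><compartment id="cell" size="1"/></listOfCompartments>
  <listOfSpecies>
   <species id="A" compartment="cell" initialConcentration="3"/>
   <species id="B" compartment="cell" initialConcentration="5"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="r1" reversible="false">
    <listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="1"/></listOfProducts>
    <kineticLaw>
     <math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><times/><ci>k1</ci><ci>A</ci></apply>
     </math>
     <listOfLocalParameters><localParameter id="k1" value="2"/></listOfLocalParameters>
    </kineticLaw>
   </reaction>
  </listOfReactions>
 </model>
</sbml>', path)
}

sbml_reversible <- function(path) {
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
 <model id="rev">
  <listOfCompartments><compartment id="cell" size="1"/></listOfCompartments>
  <listOfSpecies>
   <species id="A" compartment="cell" initialConcentration="1"/>
   <species id="B" compartment="cell" initialConcentration="0"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="r1" reversible="true">
    <listOfReactants><speciesReference species="A"/></listOfReactants>
    <listOfProducts><speciesReference species="B"/></listOfProducts>
    <kineticLaw>
     <math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><minus/>
       <apply><times/><ci>kf</ci><ci>A</ci></apply>
       <apply><times/><ci>kr</ci><ci>B</ci></apply>
      </apply>
     </math>
     <listOfLocalParameters>
      <localParameter id="kf" value="1.5"/>
      <localParameter id="kr" value="0.5"/>
     </listOfLocalParameters>
    </kineticLaw>
   </reaction>
  </listOfReactions>
 </model>
</sbml>', path)
}

sbml_michaelis_menten <- function(path) {
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
 <model id="mm">
  <listOfCompartments><compartment id="cell" size="1"/></listOfCompartments>
  <listOfSpecies>
   <species id="S" compartment="cell" initialConcentration="1"/>
   <species id="P" compartment="cell" initialConcentration="0"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="enzymatic" reversible="false">
    <listOfReactants><speciesReference species="S"/></listOfReactants>
    <listOfProducts><speciesReference species="P"/></listOfProducts>
    <kineticLaw>
     <math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><divide/>
       <apply><times/><ci>Vmax</ci><ci>S</ci></apply>
       <apply><plus/><ci>Km</ci><ci>S</ci></apply>
      </apply>
     </math>
     <listOfLocalParameters>
      <localParameter id="Vmax" value="1"/>
      <localParameter id="Km" value="0.5"/>
     </listOfLocalParameters>
    </kineticLaw>
   </reaction>
  </listOfReactions>
 </model>
</sbml>', path)
}
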