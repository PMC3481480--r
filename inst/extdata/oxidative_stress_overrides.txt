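# Compile configuration for the oxidative stress pathway segments.
#
# The predictor choices and the conflict / don't-care cell resolutions
# below are RECONSTRUCTED so that compilation reproduces the published
# update rules of the oxidative stress network; they are not transcribed
# from any printed Karnaugh map.  Each cell line reads
#   target : <bits in declared predictor order> = value
# e.g. "ARE : 110 = 1" is the cell Nrf2=1, Bach1=1, ARE=0: when both the
# activator Nrf2 and the repressor Bach1 are up while the antioxidant
# response is still off, Nrf2 is taken to win (it is relocating into the
# nucleus while Bach1 is relocating out), so ARE turns on next step.
input Stress
const SMP = 1
order ROS Keap1 PKC Nrf2 Bach1 ARE
output ARE

# ROS is driven by the exogenous stress and quenched by the antioxidant
# response; Stress never appears in a segment, so it is declared here.
predictors ROS : Stress ARE
ROS : 00 = 0
ROS : 10 = 1

# Keap1 regenerates from its own previous level as well as from Nrf2.
predictors Keap1 : ROS Nrf2 Keap1
Keap1 : 000 = 0
Keap1 : 001 = 1

predictors ARE : Nrf2 Bach1 ARE

# PKC: the two segments conflict when ROS and ARE are both up
# (detoxification wins); the stress-free, response-free cell stays off.
PKC : 00 = 0
PKC : 11 = 0

# Nrf2: liberated by Keap1 loss or activated by PKC; PKC wins the
# conflict cell where both are up.
Nrf2 : 11 = 1

# ARE: the SMP homodimer segment down-regulates every cell, so all four
# Nrf2=1 cells are conflicts; Nrf2 prevails unless the response is
# already on and Bach1 is competing for the element.
ARE : 100 = 1
ARE : 101 = 1
ARE : 110 = 1
ARE : 111 = 0
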