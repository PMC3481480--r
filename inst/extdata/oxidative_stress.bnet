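# Oxidative stress response Boolean network (Nrf2-Keap1-ARE axis).
# State bit order [ROS Keap1 PKC Nrf2 Bach1 ARE], first bit most
# significant; SMP (small Maf proteins) is ubiquitously expressed and
# modeled as a constant-1 node outside the state vector.
input Stress
const SMP = 1
order ROS Keap1 PKC Nrf2 Bach1 ARE
node ROS = Stress & !ARE
node Keap1 = !ROS & (Nrf2 | Keap1)
node PKC = ROS & !ARE
node Nrf2 = PKC | !Keap1
node Bach1 = !ROS
node ARE = Nrf2 & (!ARE | !Bach1)
output ARE
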