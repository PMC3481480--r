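# Timed pathway segments of the oxidative stress response (all t=1).
# Plain form:    P1[,P2[,P3]] | v1[,v2[,v3]] => T=v @t
# Negating form: P ~> T @t   (T follows the complement of P)
ROS | 1 => Keap1=0 @1
ROS | 1 => PKC=1 @1
ROS ~> Bach1 @1
Keap1 ~> Nrf2 @1
Nrf2,ROS | 1,0 => Keap1=1 @1
PKC | 1 => Nrf2=1 @1
Bach1,SMP | 1,1 => ARE=0 @1
Nrf2,SMP | 1,1 => ARE=1 @1
SMP | 1 => ARE=0 @1
ARE | 1 => SMP=1 @1
ARE | 1 => ROS=0 @1
ARE | 1 => PKC=0 @1
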