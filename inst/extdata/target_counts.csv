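node_id,metabolite,target_number,identification
N1,M61,102,dimethylated product of oxyresveratrol
N2,M50,78,"2,4,3',5'-Tetrahydroxybibenzyl"
N3,M70,76,Oxyresveratrol
N4,M49,65,dehydrogenation product of oxyresveratrol
N5,M42,19,hydrogenation and sulfation product of oxyresveratrol
N6,M1,7,beta-D-glucopyranosiduronic acid 3-hydroxyphenyl
N7,M48,3,sulfation product of oxyresveratrol
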