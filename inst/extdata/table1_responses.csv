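"species","n","effect","se","scale_km"
"Canada Warbler",7010,-1.49,0.5,1
"Black-throated Blue Warbler",9222,-1.19,0.21,1
"Winter Wren",5851,-1.16,0.27,1
"Louisiana Waterthrush",13732,-1.12,0.18,0.5
"Least Flycatcher",10473,-1.09,0.21,1
"Hermit Thrush",11059,-1.06,0.1,2
"Pine Warbler",5849,-0.95,0.31,16
"Magnolia Warbler",8610,-0.91,0.13,1
"Northern Parula",8077,-0.9,0.2,1
"Yellow-bellied Sapsucker",6440,-0.87,0.12,8
"Mourning Warbler",2909,-0.86,0.4,0.5
"Worm-eating Warbler",3047,-0.82,0.32,0.2
"Dark-eyed Junco",9295,-0.81,0.1,8
"Brown Creeper",3279,-0.78,0.23,0.2
"Blackburnian Warbler",9241,-0.72,0.1,1
"Golden-winged Warbler",2010,-0.7,0.32,2
"Black-throated Green Warbler",11842,-0.68,0.07,1
"Common Raven",13101,-0.66,0.16,2
"Ovenbird",13701,-0.62,0.05,16
"Veery",13071,-0.61,0.06,0.2
"Golden-crowned Kinglet",3701,-0.58,0.31,2
"Yellow-throated Vireo",9641,-0.56,0.14,6
"Chestnut-sided Warbler",13494,-0.54,0.06,1
"Hooded Warbler",6050,-0.54,0.13,0.2
"Swamp Sparrow",7987,-0.52,0.18,16
"Great Crested Flycatcher",13748,-0.48,0.1,16
"Blue-headed Vireo",11593,-0.44,0.08,1
"Cerulean Warbler",6782,-0.44,0.14,6
"Acadian Flycatcher",13761,-0.39,0.06,0.2
"Scarlet Tanager",7540,-0.34,0.04,0.2
"Blue-gray Gnatcatcher",10547,-0.32,0.08,0.5
"Rose-breasted Grosbeak",11491,-0.31,0.06,0.5
"Yellow-billed Cuckoo",16313,-0.29,0.06,1
"American Redstart",16208,-0.28,0.04,0.2
"Common Yellowthroat",16407,-0.26,0.03,0.2
"Eastern Wood-Pewee",16407,-0.24,0.03,0.2
"Pileated Woodpecker",15378,-0.24,0.07,6
"Black-and-white Warbler",7204,-0.2,0.07,0.2
"Red-eyed Vireo",11682,-0.19,0.02,0.5
"Hairy Woodpecker",16407,-0.18,0.07,0.2
"Cedar Waxwing",13776,-0.13,0.06,16
"Tree Swallow",16144,-0.12,0.14,2
"Ruby-throated Hummingbird",15391,-0.06,0.06,6
"Prairie Warbler",8658,-0.03,0.08,0.2
"Red-breasted Nuthatch",3743,0.01,0.06,0.5
"Purple Finch",10288,0.02,0.05,10
"Black-capped Chickadee",14186,0.03,0.03,10
"White-breasted Nuthatch",15231,0.03,0.03,2
"Indigo Bunting",15085,0.08,0.02,8
"Eastern Phoebe",13776,0.09,0.09,16
"Yellow-throated Warbler",1150,0.13,0.34,4
"Chipping Sparrow",16407,0.17,0.02,0.2
"Wood Thrush",14737,0.19,0.04,10
"American Crow",13776,0.22,0.05,16
"Tufted Titmouse",13776,0.25,0.04,16
"Northern Flicker",13776,0.45,0.08,16
"Kentucky Warbler",3525,0.49,0.47,12
"Eastern Towhee",13776,0.74,0.06,16
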