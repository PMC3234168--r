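# Fixed neutral background vocabulary for the synthetic-corpus
# generator: 500 everyday English words whose Porter stems are
# disjoint from the seed lexicon (verified at build time).
# One word per line; '#' starts a comment.
actor
afternoon
airport
ancient
ankle
anniversary
answer
ant
apartment
apple
april
arm
arrange
arrive
article
ask
august
aunt
autumn
avenue
bag
bake
baker
bakery
ball
ballet
banana
bark
barrel
basket
bathroom
battery
beach
bean
bear
bed
bedroom
bee
beef
belt
bench
bend
berry
bird
birthday
bitter
black
blanket
blue
boil
bone
book
boot
border
borrow
bottle
boulder
bowl
box
brake
branch
bread
breakfast
breeze
bridge
broad
brother
brown
bucket
build
building
bush
butcher
butter
butterfly
button
buy
buzz
cable
cake
calendar
calm
camera
cap
card
carnival
carpenter
carrot
carry
cash
cat
catch
cave
ceiling
celebration
certificate
chair
chapter
charger
chat
checkers
cheek
cheerful
cheese
chef
cherry
chess
chest
chew
chicken
chime
chin
choir
chop
cinema
circus
city
clay
clean
cliff
climb
clinic
clock
close
cloud
coast
coat
coffee
coin
cold
collar
computer
concert
content
cook
cookie
cool
corn
corner
cost
count
country
county
cousin
cow
crate
crawl
crease
cup
dance
dancer
daughter
dawn
december
deep
deer
depart
describe
desert
dinner
diploma
discuss
district
doctor
dog
doll
dollar
dolphin
domino
door
dot
draw
drawing
dream
dress
drink
driver
drop
drum
duck
dusk
dust
eagle
early
east
eat
echo
egg
elbow
electrician
elephant
engine
enormous
envelope
essay
evening
exam
explain
explore
eyebrow
eyelash
family
farmer
fast
father
february
fence
fern
festival
field
finger
fish
fisherman
fix
floor
flour
flower
flute
fog
fold
folder
foot
forehead
forest
forget
fork
fountain
fox
fresh
friday
friend
friendly
frog
frost
fry
game
garage
garden
gardener
garlic
gate
gentle
giggle
glad
glove
goat
golden
goose
grade
grandfather
grandmother
grape
grass
gravel
gray
green
guest
guitar
hail
hair
hand
handle
happy
harbor
hard
hat
hawk
head
headphone
heart
heavy
hedge
hill
hip
hold
holiday
homework
honey
hop
horse
hospital
hot
hour
house
huge
hum
ice
imagine
instant
island
jacket
jam
january
jar
jaw
journal
journey
joyful
july
jump
june
keyboard
kind
kitchen
kite
knee
knife
lake
lamb
lamp
large
late
laugh
lawn
leaf
learn
leg
lemon
lend
lesson
letter
lettuce
librarian
library
lift
light
lightning
lion
lizard
long
lunch
lung
magazine
map
marble
march
market
may
meadow
measure
melody
melon
mention
merry
midnight
mild
milk
minute
mist
modern
moment
monday
monkey
month
morning
moss
mother
mountain
mouse
mug
murmur
muscle
museum
music
napkin
narrow
nation
neck
neighbor
nephew
new
newspaper
niece
night
noon
north
notebook
novel
november
number
nurse
ocean
october
office
old
onion
open
opera
orange
organize
owl
page
paint
painter
painting
paper
parade
paragraph
parent
park
pasta
patient
pattern
pay
pea
peach
pebble
pedal
pen
pencil
penny
pepper
petal
pharmacy
phone
photograph
piano
picnic
pie
pig
pillow
pilot
pink
plaid
plate
play
pleasant
plum
plumber
pocket
poem
poet
polish
polite
pond
pork
potato
pour
prairie
price
printer
pull
purple
purse
push
puzzle
question
quick
quiet
rabbit
radio
rain
rainbow
rapid
rat
read
recent
red
region
relax
remain
remember
repair
reply
rest
return
rhythm
rice
riddle
ring
river
road
roam
roast
robin
rock
roll
roof
root
rough
run
sailor
salad
salmon
salt
salty
sand
sandal
saturday
save
scarf
school
screen
sculpture
sea
season
seat
second
seed
sell
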